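test_that("IBD-mixture likelihood matches hand evaluation at one locus", {
  # both individuals AA at a biallelic locus with p = 0.5, no error
  x <- geno_from_labels(rbind("A/A", "A/A", "A/B", "B/B"), pops = rep("p", 4),
                        ids = c("i1", "i2", "i3", "i4"))
  m <- relationship_model(error_rate = 0)
  f <- list(c(0.5, 0.5))
  expect_equal(exp(pair_class_likelihood(x, "i1", "i2", "unrelated", m, f)),
               0.0625)
  expect_equal(exp(pair_class_likelihood(x, "i1", "i2", "fullsib", m, f)),
               0.140625)
  expect_equal(exp(pair_class_likelihood(x, "i1", "i2", "halfsib", m, f)),
               0.5 * 0.0625 + 0.5 * 0.125)
  # opposite homozygotes exclude parent-offspring outright
  expect_identical(pair_class_likelihood(x, "i1", "i4", "parentoffspring", m, f),
                   -Inf)
  # at error rate 1 every class collapses to the uniform HW genotype model
  m1 <- relationship_model(error_rate = 1)
  lls <- vapply(names(ibd_coefficients()), function(cl)
    pair_class_likelihood(x, "i1", "i3", cl, m1, f), 1)
  expect_true(all(abs(lls - lls[1]) < 1e-12))
})

test_that("likelihood ties break toward the less related class", {
  # at error rate 1 every class reduces to the same HW model: an exact tie
  x <- geno_from_labels(rbind("A/B", "A/B", "A/A", "B/B"), pops = rep("p", 4),
                        ids = paste0("i", 1:4))
  m <- relationship_model(error_rate = 1)
  s <- suppressWarnings(classify_pairs(x, "p", model = m))
  expect_true(all(s$pairs$class == "unrelated"))
})

test_that("duplicate genotypes classify as full sibs (no twin class)", {
  set.seed(2)
  p <- runif(300, 0.1, 0.9)
  g <- rbinom(300, 2, p)
  a1 <- rbind(ifelse(g >= 1, 1L, 2L), ifelse(g >= 1, 1L, 2L),
              rbinom(300, 1, p) + 1L)
  a2 <- rbind(ifelse(g == 2, 1L, 2L), ifelse(g == 2, 1L, 2L),
              rbinom(300, 1, p) + 1L)
  x <- genotype_dataset(a1, pmax(a1, a2), c("d1", "d2", "o"), rep("p", 3),
                        data.frame(locus_id = paste0("l", 1:300),
                                   marker_class = "SNP"),
                        rep(list(c("A", "C")), 300))
  s <- classify_pairs(x, "p", relationship_model(error_rate = 0.05))
  dup <- s$pairs[s$pairs$id1 == "d1" & s$pairs$id2 == "d2", ]
  expect_identical(dup$class, "fullsib")
})

test_that("cross-population pairs are refused", {
  x <- random_geno(6, rep(2, 25), seed = 3, pops = rep(c("a", "b"), each = 3))
  expect_error(pair_class_likelihood(x, "i01", "i04", "fullsib"),
               "within-population")
})

test_that("log-likelihood separation grows with locus count for truth pairs", {
  set.seed(6)
  freqs <- runif(400, 0.2, 0.8)
  sim <- simulate_relationship_pairs(30, "unrelated", freqs, seed = 6)
  m <- relationship_model(error_rate = 0)
  fr <- lapply(freqs, function(p) c(p, 1 - p))
  gap <- function(nl) {
    d <- sim$data[, seq_len(nl)]
    mean(vapply(seq_len(30), function(p)
      pair_class_likelihood(d, sim$pairs$id1[p], sim$pairs$id2[p],
                            "unrelated", m, fr[seq_len(nl)]) -
      pair_class_likelihood(d, sim$pairs$id1[p], sim$pairs$id2[p],
                            "fullsib", m, fr[seq_len(nl)]), 1))
  }
  gaps <- vapply(c(50, 200, 400), gap, 1)
  expect_true(all(diff(gaps) > 0))
  # roughly linear growth: doubling loci about doubles the mean gap
  expect_equal(gaps[3] / gaps[2], 2, tolerance = 0.35)
})

test_that("a simulated full-sib family is recovered intact", {
  # common variants only: allele-frequency estimates from 30 individuals are
  # precise enough for the full-sib/half-sib margin (rare alleles are not --
  # a documented limitation of pairwise likelihoods with plug-in frequencies)
  cfg <- sim_config(n_populations = 1, n_individuals_per_pop = 30,
                    divergence_F = 0.05, snp_maf_floor = 0.3,
                    n_msat_loci = 0, n_snp_loci = 1000,
                    family_plan = data.frame(population = "pop_1",
                                             relationship = "fullsib",
                                             family_size = 4),
                    error_rate_snp = 0.05,
                    missing_rate_individual = 0, missing_rate_locus = 0,
                    seed = 33)
  sim <- simulate_dataset(cfg)
  model <- relationship_model(
    error_rate = c(SNP = allele_to_genotype_error(0.05), microsatellite = 1e-4))
  s <- classify_pairs(sim$data, "pop_1", model,
                      classes = c("unrelated", "halfsib", "fullsib"))
  tr <- relationship_pairs(sim$truth, "pop_1")
  key <- paste(s$pairs$id1, s$pairs$id2)
  tkey <- paste(tr$id1, tr$id2)
  fs_pairs <- tkey[tr$relationship == "fullsib"]
  expect_identical(unique(s$pairs$class[key %in% fs_pairs]), "fullsib")
  fam_sizes <- vapply(s$families, length, 1L)
  expect_identical(fam_sizes, 4L)                  # one family of four
})
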