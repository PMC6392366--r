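test_that("the same seed reproduces the dataset bit for bit", {
  cfg <- sim_config(n_populations = 2, n_individuals_per_pop = c(8, 8),
                    divergence_F = c(0.1, 0.1), n_msat_loci = 3,
                    n_snp_loci = 40,
                    family_plan = data.frame(population = "pop_1",
                                             relationship = "fullsib",
                                             family_size = 3),
                    seed = 13)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(serialize(s1$data, NULL), serialize(s2$data, NULL))
  expect_identical(s1$truth$pedigree, s2$truth$pedigree)
})

test_that("zero divergence gives identical population frequencies", {
  cfg <- sim_config(n_populations = 3, n_individuals_per_pop = c(4, 4, 4),
                    divergence_F = c(0, 0, 0), n_msat_loci = 2, n_snp_loci = 5,
                    family_plan = NULL, seed = 3)
  tr <- simulate_dataset(cfg)$truth
  for (m in tr$true_pop_freqs)
    expect_true(all(abs(m - m[, 1]) < 1e-12))
})

test_that("without error or missingness offspring are Mendelian-consistent", {
  cfg <- sim_config(n_populations = 1, n_individuals_per_pop = 10,
                    divergence_F = 0.1, n_msat_loci = 4, n_snp_loci = 30,
                    family_plan = data.frame(
                      population = "pop_1",
                      relationship = c("fullsib", "halfsib"),
                      family_size = c(4, 3)),
                    error_rate_snp = 0, error_rate_msat = 0,
                    missing_rate_individual = 0, missing_rate_locus = 0,
                    seed = 9)
  sim <- simulate_dataset(cfg)
  x <- sim$data; ped <- sim$truth$pedigree
  expect_false(anyNA(x$a1))
  pg <- sim$truth$parent_genotypes
  off <- which(!is.na(ped$sire))
  expect_gt(length(off), 0)
  for (i in off) {
    si <- match(ped$sire[i], pg$ids); di <- match(ped$dam[i], pg$ids)
    for (l in seq_len(n_loci(x))) {
      expect_true(mendel_consistent(
        c(x$a1[i, l], x$a2[i, l]),
        c(pg$a1[si, l], pg$a2[si, l]),
        c(pg$a1[di, l], pg$a2[di, l])))
    }
  }
})

test_that("pedigree truth labels pairs symmetrically and correctly", {
  cfg <- sim_config(n_populations = 1, n_individuals_per_pop = 9,
                    divergence_F = 0.1, n_msat_loci = 0, n_snp_loci = 10,
                    family_plan = data.frame(
                      population = "pop_1",
                      relationship = c("fullsib", "halfsib"),
                      family_size = c(3, 3)),
                    seed = 2)
  tr <- simulate_dataset(cfg)$truth
  pr <- relationship_pairs(tr, "pop_1")
  expect_identical(pair_relationship(tr, pr$id1, pr$id2),
                   pair_relationship(tr, pr$id2, pr$id1))
  expect_equal(sum(pr$relationship == "fullsib"), choose(3, 2))
  expect_equal(sum(pr$relationship == "halfsib"), choose(3, 2))
  ped <- tr$pedigree
  fs <- pr[pr$relationship == "fullsib", ][1, ]
  expect_identical(ped$sire[ped$id == fs$id1], ped$sire[ped$id == fs$id2])
  expect_identical(ped$dam[ped$id == fs$id1], ped$dam[ped$id == fs$id2])
  hs <- pr[pr$relationship == "halfsib", ][1, ]
  expect_identical(ped$sire[ped$id == hs$id1], ped$sire[ped$id == hs$id2])
  expect_false(identical(ped$dam[ped$id == hs$id1], ped$dam[ped$id == hs$id2]))
})

test_that("impossible family plans and bad configs are rejected", {
  expect_error(sim_config(n_populations = 1, n_individuals_per_pop = 3,
                          divergence_F = 0.1,
                          family_plan = data.frame(population = "pop_1",
                                                   relationship = "fullsib",
                                                   family_size = 5)),
               "larger than population")
  expect_error(sim_config(n_populations = 1, n_individuals_per_pop = 5,
                          divergence_F = 1.2, family_plan = NULL), "rate|\\[0, 1")
  expect_error(sim_config(msat_allele_range = c(1, 10), family_plan = NULL),
               "msat_allele_range")
})

test_that("Wright-Fisher drift fixes loci at tiny Ne and bounds sampling", {
  wf <- simulate_wright_fisher(2, n_generations = 60, n_loci = 100,
                               sample_size = 2, seed = 4)
  poly <- vapply(seq_len(n_loci(wf)), function(l)
    length(unique(c(wf$a1[, l], wf$a2[, l]))) > 1, logical(1))
  expect_lt(mean(poly), 0.25)                  # most loci fixed
  expect_error(simulate_wright_fisher(10, 5, 10, 11, seed = 1),
               "cannot sample")
  expect_error(simulate_wright_fisher(1, 5, 10, 1, seed = 1), "true_Ne")
})

test_that("simulated Bxy orders fullsib > halfsib > unrelated group means", {
  cfg <- sim_config(n_populations = 1, n_individuals_per_pop = 24,
                    divergence_F = 0.1, n_msat_loci = 0, n_snp_loci = 400,
                    family_plan = data.frame(
                      population = "pop_1",
                      relationship = c("fullsib", "halfsib"),
                      family_size = c(5, 5)),
                    seed = 31)
  sim <- simulate_dataset(cfg)
  bm <- bxy_matrix(sim$data)
  pr <- relationship_pairs(sim$truth, "pop_1")
  vals <- bm$bxy[cbind(match(pr$id1, rownames(bm$bxy)),
                       match(pr$id2, colnames(bm$bxy)))]
  means <- tapply(vals, pr$relationship, mean, na.rm = TRUE)
  expect_gt(means[["fullsib"]], means[["halfsib"]])
  expect_gt(means[["halfsib"]], means[["unrelated"]])
})

test_that("relationship-pair generator matches its IBD class", {
  # parent-offspring pairs always share an allele when error-free
  po <- simulate_relationship_pairs(40, "parentoffspring",
                                    runif(60, 0.2, 0.8), seed = 6)
  x <- po$data
  for (p in seq_len(nrow(po$pairs))) {
    i <- match(po$pairs$id1[p], x$ids); j <- match(po$pairs$id2[p], x$ids)
    share <- mapply(function(a, b, c, d) length(intersect(c(a, b), c(c, d))) > 0,
                    x$a1[i, ], x$a2[i, ], x$a1[j, ], x$a2[j, ])
    expect_true(all(share))
  }
  # unrelated pairs have mean sharing near the HW expectation, below fullsib
  un <- simulate_relationship_pairs(60, "unrelated", runif(200, .2, .8), seed = 7)
  fs <- simulate_relationship_pairs(60, "fullsib", runif(200, .2, .8), seed = 7)
  mb <- function(s) mean(mapply(function(i, j) bxy_pair(s$data, i, j),
                                s$pairs$id1, s$pairs$id2))
  expect_gt(mb(fs), mb(un) + 0.05)
})
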