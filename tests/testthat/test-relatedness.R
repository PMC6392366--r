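test_that("allele-sharing scores follow the multiset-intersection table", {
  x <- geno_from_labels(
    rbind(c("a/a", "a/b", "a/b", "a/a", "a/b"),
          c("a/a", "a/b", "a/c", "b/b", "c/d")),
    pops = c("p", "p"), marker_class = "microsatellite", ids = c("u", "v"))
  expect_equal(bxy_pair(x[, 1], "u", "v"), 1)       # AA vs AA
  expect_equal(bxy_pair(x[, 2], "u", "v"), 1)       # AB vs AB
  expect_equal(bxy_pair(x[, 3], "u", "v"), 0.5)     # AB vs AC
  expect_equal(bxy_pair(x[, 4], "u", "v"), 0)       # AA vs BB
  expect_equal(bxy_pair(x[, 5], "u", "v"), 0)       # AB vs CD
  expect_equal(bxy_pair(x, "u", "v"), mean(c(1, 1, 0.5, 0, 0)))
  # AA vs AB shares half
  y <- geno_from_labels(rbind("a/a", "a/b"), pops = c("p", "p"),
                        ids = c("u", "v"))
  expect_equal(bxy_pair(y, "u", "v"), 0.5)
})

test_that("Bxy is invariant to allele relabeling and locus order", {
  x <- random_geno(6, c(3, 4, 2, 5), seed = 9)
  b0 <- bxy_matrix(x, min_shared = 1)$bxy
  perm <- c(3, 1, 4, 2)
  b1 <- bxy_matrix(x[, perm], min_shared = 1)$bxy
  expect_equal(b0, b1)
  y <- x
  set.seed(4)
  for (l in seq_len(n_loci(y))) {
    k <- length(y$alleles[[l]]); pm <- sample(k)
    y$a1[, l] <- pm[y$a1[, l]]; y$a2[, l] <- pm[y$a2[, l]]
  }
  y <- genotype_dataset(y$a1, y$a2, y$ids, y$pops, y$loci, y$alleles)
  expect_equal(bxy_matrix(y, min_shared = 1)$bxy, b0)
})

test_that("matrix path agrees with the pairwise multiset oracle", {
  x <- random_geno(7, c(2, 4, 3, 2, 6), seed = 14, miss = 0.15)
  bm <- bxy_matrix(x, min_shared = 1)
  for (i in 1:6) for (j in (i + 1):7) {
    expect_equal(bm$bxy[i, j], oracle_bxy(x, x$ids[i], x$ids[j]),
                 tolerance = 1e-12,
                 label = sprintf("pair %d-%d", i, j))
  }
  # pairs below the shared-locus floor are NA
  y <- random_geno(4, rep(2, 6), seed = 2)
  y$a1[1, 1:4] <- NA; y$a2[1, 1:4] <- NA
  bm2 <- bxy_matrix(genotype_dataset(y$a1, y$a2, y$ids, y$pops, y$loci,
                                     y$alleles), min_shared = 5)
  expect_true(is.na(bm2$bxy[1, 2]))
})

test_that("subset precision is zero at the full panel and exact at size 1", {
  x <- random_geno(6, c(3, 4), seed = 21)
  pc <- subset_precision(x, subset_sizes = c(1, 2), n_replicates = 400,
                         seed = 8)
  full_rows <- pc$curve[pc$curve$subset_size == 2, ]
  expect_true(all(full_rows$mean_abs_difference == 0))
  # exhaustive enumeration of the two possible single-locus subsets
  bm <- bxy_matrix(x, min_shared = 1)$bxy
  full <- bm[upper.tri(bm)]
  vals <- vapply(1:2, function(l) {
    b <- bxy_matrix(x[, l], min_shared = 1)$bxy
    mean(abs(b[upper.tri(b)] - full))
  }, 1)
  ones <- pc$curve$mean_abs_difference[pc$curve$subset_size == 1]
  expect_true(all(vapply(ones, function(v)
    any(abs(v - vals) < 1e-12), logical(1))))
  expect_equal(mean(ones), mean(vals), tolerance = 0.05)
  expect_error(subset_precision(x, 0), "subset sizes")
  expect_error(subset_precision(x, 3), "exceeds")
})

test_that("precision improves with subset size on simulated panels", {
  cfg <- sim_config(n_populations = 1, n_individuals_per_pop = 16,
                    divergence_F = 0.1, n_msat_loci = 0, n_snp_loci = 200,
                    family_plan = NULL, seed = 51)
  x <- simulate_dataset(cfg)$data
  pc <- subset_precision(x, c(2, 8, 32, 128), n_replicates = 100, seed = 3)
  expect_true(all(diff(pc$summary$mean) < 0))
})
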