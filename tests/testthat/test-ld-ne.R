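test_that("perfect association between two loci gives r2 of exactly 1", {
  # allele-count patterns identical at both loci (A1 always travels with B1)
  pat <- c("A/A", "A/A", "A/C", "A/C", "A/C", "A/C", "C/C", "C/C")
  x <- geno_from_labels(cbind(pat, pat), pops = rep("p", 8))
  b <- suppressWarnings(burrows_r2(x, maf_cutoff = 0))
  expect_equal(b$r2_mean, 1)
  expect_equal(b$n_pairs, 1L)
})

test_that("closed-form Ne inversion reproduces hand-evaluated values", {
  # drift r2 of 1/150 at S >= 30
  r2 <- 1 / 150 + r2_sample_expectation(50)
  est <- ne_from_r2(r2, 50)
  expect_equal(est$r2_drift, 1 / 150, tolerance = 1e-12)
  expect_equal(est$ne_raw, (1 / 3 + sqrt(1 / 9 - 2.76 / 150)) / (2 / 150),
               tolerance = 1e-10)
  expect_equal(est$ne_raw, 47.84, tolerance = 1e-3)
  # boundary: r2 at exactly the sampling expectation is infinite
  expect_identical(ne_from_r2(r2_sample_expectation(40), 40)$ne_raw, Inf)
  expect_identical(ne_from_r2(0.001, 40)$ne_raw, Inf)  # below expectation
  # monotone decreasing in r2 where finite
  r2s <- seq(0.03, 0.08, by = 0.005)
  nes <- vapply(r2s, function(r) ne_from_r2(r, 40)$ne_raw, 1)
  fin <- is.finite(nes)
  expect_true(all(diff(nes[fin]) < 0))
})

test_that("chromosome-number bias correction matches the published divisor", {
  expect_equal(chromosome_bias_factor(40), 0.906, tolerance = 5e-4)
  expect_equal(chromosome_bias_correction(53, 40), 58.50, tolerance = 5e-3)
  expect_identical(chromosome_bias_correction(Inf, 40), Inf)
  expect_error(chromosome_bias_correction(10, 1), "n_chromosomes")
  # correction inflates finite estimates for fewer than ~61 chromosomes
  for (ch in c(2, 10, 40, 60)) expect_gt(chromosome_bias_correction(100, ch), 100)
  expect_lt(chromosome_bias_correction(100, 70), 100)
})

test_that("burrows_r2 equals the brute-force indicator-covariance oracle", {
  for (seed in 1:6) {
    k <- list(c(2, 2, 2), c(2, 3, 2, 5), c(4, 6))[[seed %% 3 + 1]]
    x <- random_geno(8, k, seed = seed)
    expect_equal(suppressWarnings(burrows_r2(x, maf_cutoff = 0.02))$r2_mean,
                 oracle_burrows_r2(x, maf_cutoff = 0.02), tolerance = 1e-12,
                 label = sprintf("seed %d", seed))
  }
})

test_that("missing-data path agrees with the complete-data path", {
  x <- random_geno(10, c(2, 2, 3, 2), seed = 3)
  full <- burrows_r2(x, maf_cutoff = 0.02)
  y <- x
  y$a1[1, 1] <- NA; y$a2[1, 1] <- NA       # one missing call forces slow path
  miss <- burrows_r2(y, maf_cutoff = 0.02)
  expect_equal(miss$n_pairs, full$n_pairs)
  # pairs not involving locus 1 are untouched
  expect_equal(burrows_r2(y[, 2:4], maf_cutoff = 0.02)$r2_mean,
               burrows_r2(x[, 2:4], maf_cutoff = 0.02)$r2_mean,
               tolerance = 1e-12)
  # pairs with too little overlap are skipped and counted
  z <- x
  z$a1[1:8, 2] <- NA; z$a2[1:8, 2] <- NA
  z$a1[9:10, 2] <- 1L; z$a2[9:10, 2] <- c(1L, 2L)   # keep locus polymorphic
  z <- genotype_dataset(z$a1, z$a2, z$ids, z$pops, z$loci, z$alleles)
  b <- burrows_r2(z, maf_cutoff = 0, min_overlap = 4)
  expect_gt(b$n_skipped, 0)
})

test_that("jackknife interval brackets the point estimate", {
  wf <- simulate_wright_fisher(40, n_generations = 25, n_loci = 150,
                               sample_size = 25, seed = 12)
  e <- ld_ne(wf, n_chromosomes = 40, ci = TRUE)
  expect_true(e$ci_low <= e$ne_raw)
  expect_true(e$ci_high >= e$ne_raw)
  expect_equal(e$ne_corrected, e$ne_raw / chromosome_bias_factor(40))
  expect_error(ne_jackknife_ci(wf[1:4, ]), ">= 5")
})

test_that("independent loci carry only the sampling expectation", {
  set.seed(20)
  n <- 50; L <- 150
  p <- runif(L, 0.2, 0.8)
  a1 <- matrix(rbinom(n * L, 1, rep(p, each = n)) + 1L, n, L)
  a2 <- matrix(rbinom(n * L, 1, rep(p, each = n)) + 1L, n, L)
  x <- genotype_dataset(a1, a2, paste0("i", 1:n), rep("p", n),
                        data.frame(locus_id = paste0("l", 1:L),
                                   marker_class = "SNP"),
                        rep(list(c("A", "C")), L))
  b <- burrows_r2(x)
  expect_equal(b$r2_mean, r2_sample_expectation(n), tolerance = 0.15)
})
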