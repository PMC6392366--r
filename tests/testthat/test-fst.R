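test_that("Nei F_ST hits its analytic endpoints", {
  # populations fixed for alternative alleles at every locus
  fixed <- geno_from_labels(
    cbind(rep(c("A/A", "C/C"), each = 4), rep(c("G/G", "T/T"), each = 4)),
    pops = rep(c("p1", "p2"), each = 4))
  expect_equal(nei_fst(fixed), 1)
  # identical allele-frequency composition in both populations
  block <- c(rep("A/A", 4), rep("A/C", 8), rep("C/C", 4))
  same <- geno_from_labels(cbind(c(block, block)),
                           pops = rep(c("p1", "p2"), each = 16))
  expect_equal(nei_fst(same), 0)
  # one biallelic locus, p1 = 1.0, p2 = 0.5: H_S = 0.25, H_T = 0.375
  x <- geno_from_labels(cbind(c(rep("A/A", 4), "A/A", "A/A", "C/C", "C/C")),
                        pops = rep(c("p1", "p2"), each = 4))
  expect_equal(nei_fst(x), 1 / 3)
})

test_that("F_ST is invariant to allele and population relabeling", {
  x <- random_geno(16, c(2, 3, 4, 2), seed = 77,
                   pops = rep(c("p1", "p2"), each = 8))
  f0 <- nei_fst(x)
  # permute allele labels (indices) at every locus
  y <- x
  set.seed(1)
  for (l in seq_len(n_loci(y))) {
    k <- length(y$alleles[[l]])
    perm <- sample(k)
    y$a1[, l] <- perm[y$a1[, l]]; y$a2[, l] <- perm[y$a2[, l]]
  }
  y <- genotype_dataset(y$a1, y$a2, y$ids, y$pops, y$loci, y$alleles)
  expect_equal(nei_fst(y), f0, tolerance = 1e-12)
  # relabel populations
  z <- x
  z$pops <- c(p1 = "B", p2 = "A")[z$pops]
  expect_equal(nei_fst(z), f0, tolerance = 1e-12)
})

test_that("multi-locus aggregation reduces to the single-locus formula", {
  x <- random_geno(20, c(2, 3), seed = 5, pops = rep(c("p1", "p2"), each = 10))
  f1 <- nei_fst(x[, 1])
  f2 <- nei_fst(x[, 2])
  fc <- fst_components(x)
  expect_equal((fc$ht[1] - fc$hs[1]) / fc$ht[1], f1, ignore_attr = TRUE)
  expect_equal((fc$ht[2] - fc$hs[2]) / fc$ht[2], f2, ignore_attr = TRUE)
})

test_that("permutation p-values respect the floor and detect divergence", {
  cfg <- sim_config(n_populations = 2, n_individuals_per_pop = c(15, 15),
                    divergence_F = c(0.2, 0.2), n_msat_loci = 0,
                    n_snp_loci = 300, family_plan = NULL, error_rate_snp = 0,
                    missing_rate_individual = 0, missing_rate_locus = 0,
                    seed = 41)
  x <- simulate_dataset(cfg)$data
  pt <- fst_permutation_test(x, c("pop_1", "pop_2"), n_permutations = 99,
                             seed = 3)
  expect_equal(pt$p_value, 1 / 100)              # observed beats every permutation
  expect_error(fst_permutation_test(x, c("pop_1", "pop_2"),
                                    n_permutations = 0), "n_permutations")
})

test_that("fst_matrix assembles a symmetric pairwise table", {
  x <- random_geno(18, rep(2, 30), seed = 10,
                   pops = rep(c("a", "b", "c"), each = 6))
  fm <- fst_matrix(x, n_permutations = 19, seed = 2)
  expect_true(isSymmetric(unname(fm$pairwise)))
  expect_true(all(is.na(diag(fm$pairwise))))
  pv <- fm$p_values[lower.tri(fm$p_values)]
  expect_true(all(pv > 0 & pv <= 1))
})
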