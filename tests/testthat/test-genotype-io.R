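test_that("construction normalises unordered calls and validates input", {
  x <- genotype_dataset(a1 = matrix(c(2L, 1L), 2, 1), a2 = matrix(c(1L, 2L), 2, 1),
                        ids = c("a", "b"), pops = c("p", "p"),
                        loci = data.frame(locus_id = "l1", marker_class = "SNP"),
                        alleles = list(c("A", "C")))
  expect_true(all(x$a1 <= x$a2))
  expect_identical(genotype_labels(x)[, 1], c(a = "A/C", b = "A/C"))
  # SNP loci must be biallelic; half-missing calls rejected
  expect_error(genotype_dataset(matrix(1L), matrix(1L), "a", "p",
                                data.frame(locus_id = "l", marker_class = "SNP"),
                                list(c("A", "C", "G"))),
               "exactly 2 allele labels")
  expect_error(genotype_dataset(matrix(NA_integer_), matrix(1L), "a", "p",
                                data.frame(locus_id = "l", marker_class = "SNP"),
                                list(c("A", "C"))),
               "half-missing")
})

test_that("genepop round-trip preserves calls, labels and block structure", {
  sim <- simulate_dataset(sim_config(
    n_populations = 2, n_individuals_per_pop = c(6, 5),
    divergence_F = c(0.1, 0.05), n_msat_loci = 5, n_snp_loci = 0,
    family_plan = NULL, missing_rate_individual = 0.05,
    missing_rate_locus = 0.05, seed = 21))
  x <- sim$data
  path <- withr::local_tempfile(fileext = ".gen")
  write_genepop(x, path)
  y <- read_genepop(path, pop_names = unique(x$pops))
  expect_identical(genotype_labels(x), genotype_labels(y))
  expect_identical(x$ids, y$ids)
  expect_identical(x$pops, y$pops)
})

test_that("genepop parser handles missing codes and malformed files", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("title", "loc1", "loc2", "POP",
               "i1 , 100102 000000",
               "i2 , 100100 102104",
               "POP",
               "i3 , 102102 104104"), path)
  x <- read_genepop(path)
  expect_equal(length(unique(x$pops)), 2)
  expect_equal(n_individuals(x), 3)
  expect_true(is.na(x$a1[1, 2]))                 # 000000 is MISSING
  expect_identical(genotype_labels(x)[2, 1], "100/100")
  # inconsistent locus count names the line
  writeLines(c("title", "loc1", "loc2", "POP", "i1 , 100102"), path)
  expect_error(read_genepop(path), "genotypes found")
  # mixed 2- and 3-digit widths
  writeLines(c("title", "loc1", "POP", "i1 , 100102", "i2 , 0102"), path)
  expect_error(read_genepop(path), "mixed")
})

test_that("VCF round-trip preserves the genotype matrix; GT quirks handled", {
  sim <- simulate_dataset(sim_config(
    n_populations = 2, n_individuals_per_pop = c(5, 5),
    divergence_F = c(0.1, 0.1), n_msat_loci = 0, n_snp_loci = 30,
    family_plan = NULL, missing_rate_individual = 0.05,
    missing_rate_locus = 0.05, seed = 8))
  x <- subset_markers(sim$data, "SNP")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(x, path)
  y <- read_vcf(path, stats::setNames(x$pops, x$ids))
  expect_identical(genotype_labels(x), genotype_labels(y))
  expect_identical(x$pops, y$pops)

  # phased and unphased GT are the same unordered call; multiallelic skipped
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="G">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
               "1\t1\tv1\tA\tC\t.\t.\t.\tGT\t0/1\t1|0",
               "1\t2\tv2\tA\tC,T\t.\t.\t.\tGT\t0/1\t1/1",
               "1\t3\tv3\tG\tT\t.\t.\t.\tGT\t./.\t0/0"), path)
  expect_warning(z <- read_vcf(path), "multiallelic")
  expect_equal(attr(z, "skipped_multiallelic"), 1L)
  expect_equal(n_loci(z), 2)
  expect_identical(genotype_labels(z)["s1", "v1"], genotype_labels(z)["s2", "v1"])
  expect_true(is.na(z$a1["s1", "v3"]))
})

test_that("subsetting to shared individuals preserves call values", {
  x <- random_geno(8, c(2, 2, 4), seed = 5, miss = 0.1,
                   pops = rep(c("p1", "p2"), each = 4))
  keep <- c("i02", "i05", "i07")
  y <- x[keep, ]
  expect_identical(genotype_labels(x)[keep, ], genotype_labels(y))
  expect_identical(y$pops, x$pops[match(keep, x$ids)])
})
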