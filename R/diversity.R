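#' Expected heterozygosity (gene diversity)
#'
#' Plain Nei gene diversity `1 - sum(p^2)`; its theoretical maximum is 1 for
#' multiallelic loci and 0.5 for biallelic loci at p = q = 0.5. The unbiased
#' small-sample variant multiplies by `n/(n-1)` gene copies.
#'
#' @param freqs allele frequency vector (non-negative, summing to 1 within
#'   1e-9).
#' @param unbiased logical; apply the `n/(n-1)` correction.
#' @param n number of gene copies (required when `unbiased = TRUE`).
#' @return a single gene-diversity value in `[0, 1]`.
#' @export
expected_heterozygosity <- function(freqs, unbiased = FALSE, n = NULL) {
  if (length(freqs) == 0) stop("empty frequency vector")
  if (any(freqs < 0)) stop("negative allele frequency")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  he <- 1 - sum(freqs^2)
  if (unbiased) {
    if (is.null(n) || n < 2) stop("unbiased variant needs n >= 2 gene copies")
    he <- he * n / (n - 1)
  }
  he
}

#' Rarefied allelic richness
#'
#' Hypergeometric rarefaction of the allele count to a common sample of `g`
#' gene copies: `Ar = sum_a [1 - C(N - N_a, g) / C(N, g)]`, the expected number
#' of distinct alleles in a random subsample of size `g`.
#'
#' @param allele_counts per-allele gene-copy counts at one locus (one
#'   population).
#' @param g rarefaction size in gene copies, `1 <= g <= sum(allele_counts)`.
#' @return expected allele count at depth `g`; `NA` when no copies were typed.
#' @export
allelic_richness <- function(allele_counts, g) {
  N <- sum(allele_counts)
  if (N == 0) return(NA_real_)
  if (g < 1 || g > N) stop("rarefaction size g must lie in [1, total gene copies]")
  # lchoose for numerical stability at SNP-panel sample sizes
  sum(1 - exp(lchoose(N - allele_counts, g) - lchoose(N, g)))
}

#' Hardy--Weinberg equilibrium test at one locus in one population
#'
#' `chi2` is the goodness-of-fit statistic of observed genotype counts against
#' Hardy--Weinberg expectations computed from the observed allele frequencies
#' (all k(k+1)/2 genotype categories). `mc_exact` permutes the observed gene
#' copies into random diploid genotypes and uses the chi-square statistic as
#' the discrepancy measure, with
#' `p = (1 + #[statistic_perm >= statistic_obs]) / (1 + n_permutations)`.
#'
#' @param a1,a2 allele index vectors of the genotypes (one entry per
#'   individual, `NA` for missing calls), or `a1` may be a `geno_data` -- then
#'   `a2` is the locus and `pop` the population to test.
#' @param method `"chi2"` or `"mc_exact"`.
#' @param n_permutations Monte-Carlo permutations for `mc_exact`.
#' @param seed seed for the permutation stream (logged in the result).
#' @param pop population label when `a1` is a dataset.
#' @return list with `statistic`, `p_value`, `method`, `df` (chi2 only) and
#'   `reason` (`NA` unless the test is undefined, e.g. a monomorphic locus).
#' @export
hwe_test <- function(a1, a2, method = c("chi2", "mc_exact"),
                     n_permutations = 1000, seed = 1, pop = NULL) {
  method <- match.arg(method)
  if (inherits(a1, "geno_data")) {
    x <- a1; locus <- a2
    if (is.character(locus)) locus <- match(locus, x$loci$locus_id)
    rows <- if (is.null(pop)) seq_along(x$ids) else which(x$pops == pop)
    a1 <- x$a1[rows, locus]; a2 <- x$a2[rows, locus]
  }
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  if (length(a1) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, method = method,
                reason = "no genotypes"))
  als <- sort(unique(c(a1, a2)))
  if (length(als) < 2)
    return(list(statistic = NA_real_, p_value = NA_real_, method = method,
                reason = "monomorphic"))
  stat <- hwe_chi2_stat(a1, a2, als)
  k <- length(als)
  if (method == "chi2") {
    df <- k * (k + 1) / 2 - k
    return(list(statistic = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                method = method, df = df, reason = NA_character_))
  }
  set.seed(seed)
  copies <- c(a1, a2)
  n <- length(a1)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample(copies)
    s <- hwe_chi2_stat(perm[seq_len(n)], perm[n + seq_len(n)], als)
    if (s >= stat - 1e-12) exceed <- exceed + 1L
  }
  list(statistic = stat, p_value = (1 + exceed) / (1 + n_permutations),
       method = method, n_permutations = n_permutations, seed = seed,
       reason = NA_character_)
}

# chi-square GOF statistic over all genotype categories, HW expectations from
# observed allele frequencies
hwe_chi2_stat <- function(a1, a2, als) {
  n <- length(a1)
  k <- length(als)
  i1 <- match(pmin(a1, a2), als); i2 <- match(pmax(a1, a2), als)
  p <- tabulate(c(i1, i2), k) / (2 * n)
  obs <- matrix(tabulate((i2 - 1L) * k + i1, k * k), k, k)   # obs[i1, i2]
  e <- 2 * n * outer(p, p)
  diag(e) <- n * p^2
  mask <- upper.tri(e, diag = TRUE)
  ev <- e[mask]; ov <- obs[mask]
  sum(ifelse(ev > 0, (ov - ev)^2 / ev, ifelse(ov > 0, Inf, 0)))
}

#' Population diversity summary table
#'
#' Per-population allele counts, rarefied allelic richness, and expected
#' heterozygosity, with per-locus detail including Hardy--Weinberg p-values.
#' The rarefaction depth defaults, per locus, to the minimum number of typed
#' gene copies over populations (missing-aware), so populations of unequal
#' size are compared at a common depth.
#'
#' @param x a `geno_data` object.
#' @param g rarefaction size; `NULL` for the per-locus minimum across
#'   populations.
#' @param hwe_method,hwe_n_permutations,hwe_seed forwarded to [hwe_test()].
#' @return a `diversity_table`: list with `by_population` (rows mirroring the
#'   usual diversity table: total allele count, mean Ar, mean He) and
#'   `by_locus` (long data frame of per-locus, per-population statistics).
#' @export
diversity_table <- function(x, g = NULL, hwe_method = "chi2",
                            hwe_n_permutations = 1000, hwe_seed = 1) {
  pac <- pop_allele_counts(x)
  pops <- pac$pop_levels
  L <- nrow(x$loci)
  lev <- pac$locus_levels
  per <- vector("list", L * length(pops))
  r <- 0L
  for (li in seq_len(L)) {
    sel <- pac$locus_of == lev[li]
    cnt <- pac$acounts[sel, , drop = FALSE]           # k x npop
    gmin <- if (is.null(g)) max(1, min(pac$copies[li, ])) else g
    for (pi in seq_along(pops)) {
      N <- sum(cnt[, pi])
      nall <- sum(cnt[, pi] > 0)
      he <- if (N > 0) expected_heterozygosity(cnt[, pi] / N) else NA_real_
      ar <- if (N >= gmin && N > 0) allelic_richness(cnt[, pi], gmin) else NA_real_
      hw <- hwe_test(x, lev[li], method = hwe_method,
                     n_permutations = hwe_n_permutations, seed = hwe_seed,
                     pop = pops[pi])
      r <- r + 1L
      per[[r]] <- data.frame(locus_id = x$loci$locus_id[lev[li]],
                             marker_class = x$loci$marker_class[lev[li]],
                             population = pops[pi],
                             n_alleles = nall, n_copies = N,
                             Ar = ar, He = he, hwe_p = hw$p_value,
                             stringsAsFactors = FALSE)
    }
  }
  by_locus <- do.call(rbind, per)
  agg <- lapply(split(by_locus, by_locus$population), function(d) {
    data.frame(population = d$population[1],
               allele_count = sum(d$n_alleles),
               Ar_mean = mean(d$Ar, na.rm = TRUE),
               He_mean = mean(d$He, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  by_population <- do.call(rbind, agg)[match(pops, names(agg)), ]
  rownames(by_population) <- NULL
  structure(list(by_population = by_population, by_locus = by_locus),
            class = "diversity_table")
}

#' @export
print.diversity_table <- function(x, digits = 3, ...) {
  cat("Population diversity summary\n")
  print(format(x$by_population, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a diversity table as delimited text
#' @param x a `diversity_table`.
#' @param path output path; the per-locus detail goes to
#'   `<path>.loci.tsv`.
#' @export
write_diversity_table <- function(x, path) {
  utils::write.table(x$by_population, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$by_locus, paste0(path, ".loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
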