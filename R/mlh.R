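#' Standardized multilocus heterozygosity (sMLH)
#'
#' For individual i, `sMLH_i = H_i / sum_{l in typed(i)} hbar_l`, where `H_i`
#' is the number of heterozygous typed loci and `hbar_l` the mean observed
#' heterozygosity of locus l in the standardisation group. With no missing
#' data the group mean of sMLH is exactly 1. Standardisation can run across
#' the whole dataset or within populations.
#'
#' @param x a `geno_data` object.
#' @param marker_class optional marker class restriction.
#' @param by_population standardise within each population rather than across
#'   all individuals.
#' @return named numeric vector of per-individual sMLH (`NA` for individuals
#'   with no typed locus).
#' @export
smlh <- function(x, marker_class = NULL, by_population = FALSE) {
  if (!is.null(marker_class)) x <- subset_markers(x, marker_class)
  het <- het_matrix(x)
  groups <- if (by_population) x$pops else rep("all", length(x$ids))
  out <- rep(NA_real_, length(x$ids))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    hg <- het[rows, , drop = FALSE]
    hbar <- colMeans(hg, na.rm = TRUE)
    hbar[is.nan(hbar)] <- NA
    typed <- !is.na(hg)
    Hi <- rowSums(hg, na.rm = TRUE)
    denom <- typed %*% ifelse(is.na(hbar), 0, hbar)
    out[rows] <- ifelse(rowSums(typed) > 0, Hi / denom, NA)
  }
  stats::setNames(as.numeric(out), x$ids)
}

#' Heterozygosity--heterozygosity correlation (HHC)
#'
#' Per replicate, two disjoint random subsets of `subset_size` loci are drawn
#' (without replacement; leftover loci are unused that replicate), sMLH is
#' computed within each subset, and the Pearson correlation of the two sMLH
#' vectors across individuals is recorded. The distribution of r over
#' replicates measures how precisely the marker panel captures individual
#' heterozygosity; its mean rises with subset size when identity
#' disequilibrium is present and sits near zero without it.
#'
#' @param x a `geno_data` object.
#' @param subset_size loci per subset; `2 * subset_size` must not exceed the
#'   locus count. Default: half the loci.
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @param marker_class optional marker class restriction.
#' @param by_population standardisation grouping forwarded to [smlh()].
#' @return an `hhc_result`: numeric vector `r` of length `n_replicates`
#'   (replicates with zero variance in either subset are `NA` and counted in
#'   `n_degenerate`), plus settings.
#' @export
hhc <- function(x, subset_size = NULL, n_replicates = 1000, seed = 1,
                marker_class = NULL, by_population = FALSE) {
  if (!is.null(marker_class)) x <- subset_markers(x, marker_class)
  L <- nrow(x$loci)
  if (is.null(subset_size)) subset_size <- floor(L / 2)
  if (2 * subset_size > L) stop("2 * subset_size exceeds the locus count")
  if (subset_size < 1) stop("subset_size must be >= 1")
  het <- het_matrix(x)
  groups <- if (by_population) x$pops else rep("all", length(x$ids))
  n_ok <- sum(rowSums(!is.na(het)) > 0)
  if (n_ok < 3) stop("need >= 3 individuals with defined sMLH")
  set.seed(seed)
  smlh_of <- function(cols) {
    hg <- het[, cols, drop = FALSE]
    out <- rep(NA_real_, nrow(het))
    for (g in unique(groups)) {
      rows <- which(groups == g)
      h <- hg[rows, , drop = FALSE]
      hbar <- colMeans(h, na.rm = TRUE)
      hbar[is.nan(hbar)] <- 0
      typed <- !is.na(h)
      denom <- typed %*% hbar
      out[rows] <- ifelse(denom > 0, rowSums(h, na.rm = TRUE) / denom, NA)
    }
    out
  }
  r <- rep(NA_real_, n_replicates)
  for (b in seq_len(n_replicates)) {
    pick <- sample.int(L, 2 * subset_size)
    s1 <- smlh_of(pick[seq_len(subset_size)])
    s2 <- smlh_of(pick[subset_size + seq_len(subset_size)])
    ok <- !is.na(s1) & !is.na(s2)
    if (sum(ok) >= 3 && stats::sd(s1[ok]) > 0 && stats::sd(s2[ok]) > 0)
      r[b] <- stats::cor(s1[ok], s2[ok])
  }
  structure(list(r = r, subset_size = subset_size,
                 n_replicates = n_replicates,
                 n_degenerate = sum(is.na(r)), seed = seed),
            class = "hhc_result")
}

#' @export
print.hhc_result <- function(x, ...) {
  cat(sprintf("HHC: subset size %d, %d replicates (%d NA)\n",
              x$subset_size, x$n_replicates, x$n_degenerate))
  cat(sprintf("  mean r = %.3f (sd %.3f)\n", mean(x$r, na.rm = TRUE),
              stats::sd(x$r[!is.na(x$r)])))
  invisible(x)
}

#' Pearson correlation between two sMLH vectors
#'
#' Correlates per-individual sMLH measured with two marker panels over the
#' shared individuals, with `t = r * sqrt(df / (1 - r^2))`, `df = n - 2`, and
#' a two-sided p-value from the t distribution.
#'
#' @param smlh_a,smlh_b named numeric vectors (names = individual ids).
#' @return list with `r`, `t`, `df`, `p_value`, `n`.
#' @export
cross_marker_correlation <- function(smlh_a, smlh_b) {
  shared <- intersect(names(smlh_a)[!is.na(smlh_a)],
                      names(smlh_b)[!is.na(smlh_b)])
  if (length(shared) < 3) stop("need >= 3 shared individuals")
  a <- smlh_a[shared]; b <- smlh_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, t = NA_real_, df = length(shared) - 2L,
                p_value = NA_real_, n = length(shared)))
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value, n = length(shared))
}
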