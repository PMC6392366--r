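#' Nei F_ST over a set of populations
#'
#' Per locus, `H_S` is the unweighted mean over populations of the
#' within-population gene diversity `1 - sum(p^2)` and `H_T = 1 - sum(pbar^2)`
#' with `pbar` the unweighted mean allele frequency over populations.
#' Multi-locus F_ST aggregates by ratio of sums:
#' `F_ST = (sum_l H_T - sum_l H_S) / sum_l H_T`. Loci monomorphic across all
#' selected populations (or untyped in any of them) are excluded. Population
#' weights are deliberately ignored -- samples of unequal size contribute
#' equally, and negative estimates are reported as computed.
#'
#' @param x a `geno_data` object.
#' @param populations character vector of >= 2 population labels; defaults to
#'   all populations present.
#' @return F_ST estimate (scalar); `NA` with a `"reason"` attribute when no
#'   shared polymorphic locus exists.
#' @export
nei_fst <- function(x, populations = unique(x$pops)) {
  if (length(populations) < 2) stop("need >= 2 populations")
  xs <- subset_populations(x, populations)
  hc <- fst_components(xs)
  if (is.null(hc)) {
    out <- NA_real_
    attr(out, "reason") <- "no shared polymorphic locus"
    return(out)
  }
  (sum(hc$ht) - sum(hc$hs)) / sum(hc$ht)
}

# H_S/H_T core on a per-allele gene-copy count matrix (rows = allele columns,
# cols = populations); lidx maps rows to loci. NULL when no locus is usable
# (a locus needs >= 2 gene copies in every population and must be polymorphic
# across the pooled populations).
fst_core <- function(acounts, lidx) {
  copies <- rowsum(acounts, lidx)                    # L x npop gene copies
  freq <- acounts / copies[as.integer(lidx), , drop = FALSE]
  freq[!is.finite(freq)] <- NA
  sum_p2 <- rowsum(freq^2, lidx)                     # L x npop
  hs_locus <- rowMeans(1 - sum_p2)
  pbar <- rowMeans(freq)
  ht_locus <- 1 - rowsum(matrix(pbar^2, ncol = 1), lidx)[, 1]
  usable <- rowSums(copies >= 2) == ncol(copies) & ht_locus > 1e-12 &
    !is.na(hs_locus) & !is.na(ht_locus)
  if (!any(usable)) return(NULL)
  list(hs = hs_locus[usable], ht = ht_locus[usable])
}

# per-locus H_S and H_T for the populations present in x
fst_components <- function(x) {
  ex <- expand_alleles(x)
  pops <- factor(x$pops, levels = unique(x$pops))
  acounts <- t(rowsum(ex$counts, pops, na.rm = TRUE))
  lidx <- factor(ex$locus_of, levels = unique(ex$locus_of))
  fst_core(acounts, lidx)
}

#' Permutation test for pairwise F_ST
#'
#' Individuals (both alleles travelling together) are permuted between the two
#' populations with population sizes preserved;
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_permutations)`, so p is bounded
#' below by `1/(1 + n_permutations)`.
#'
#' @param x a `geno_data` object.
#' @param pop_pair character vector of two population labels.
#' @param n_permutations number of permutations (999 by convention).
#' @param seed integer seed.
#' @return list with `fst`, `p_value`, `n_permutations`.
#' @export
fst_permutation_test <- function(x, pop_pair, n_permutations = 999, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (length(pop_pair) != 2) stop("pop_pair must name two populations")
  xs <- subset_populations(x, pop_pair)
  obs <- nei_fst(xs, pop_pair)
  if (is.na(obs)) stop("pairwise F_ST not computable for this pair")
  set.seed(seed)
  n <- length(xs$ids)
  labels <- factor(xs$pops, levels = pop_pair)
  ex <- expand_alleles(xs)
  lidx <- factor(ex$locus_of, levels = unique(ex$locus_of))
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- labels[sample.int(n)]
    hc <- fst_core(t(rowsum(ex$counts, perm, na.rm = TRUE)), lidx)
    if (is.null(hc)) next
    f <- (sum(hc$ht) - sum(hc$hs)) / sum(hc$ht)
    if (f >= obs - 1e-12) exceed <- exceed + 1L
  }
  list(fst = obs, p_value = (1 + exceed) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' Global and pairwise Nei F_ST with permutation p-values
#'
#' @param x a `geno_data` object with >= 2 populations.
#' @param n_permutations permutations per pair; `0` skips the tests.
#' @param seed integer seed (each pair uses an offset of it).
#' @return an `fst_matrix`: list with `global_fst`, symmetric `pairwise`
#'   matrix, matching `p_values`, and `n_permutations`.
#' @export
fst_matrix <- function(x, n_permutations = 999, seed = 1) {
  pops <- unique(x$pops)
  if (length(pops) < 2) stop("need >= 2 populations")
  k <- length(pops)
  pw <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pv <- pw
  pair_i <- 0L
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    pair_i <- pair_i + 1L
    f <- nei_fst(x, c(pops[i], pops[j]))
    pw[i, j] <- pw[j, i] <- f
    if (n_permutations > 0 && !is.na(f)) {
      pt <- fst_permutation_test(x, c(pops[i], pops[j]), n_permutations,
                                 seed = seed + pair_i)
      pv[i, j] <- pv[j, i] <- pt$p_value
    }
  }
  structure(list(global_fst = nei_fst(x, pops), pairwise = pw, p_values = pv,
                 n_permutations = n_permutations),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Nei F_ST: global = %.*f\n", digits, x$global_fst))
  cat("pairwise (lower triangle), permutation p-values (upper):\n")
  m <- x$pairwise
  m[upper.tri(m)] <- x$p_values[upper.tri(m)]
  print(round(m, digits))
  invisible(x)
}

#' Write an F_ST matrix as a delimited lower-triangular table
#' @param x an `fst_matrix`.
#' @param path output path.
#' @export
write_fst_matrix <- function(x, path) {
  pops <- rownames(x$pairwise)
  rows <- data.frame(pop1 = character(), pop2 = character(),
                     fst = numeric(), p_value = numeric())
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1)) {
    rows <- rbind(rows, data.frame(pop1 = pops[i], pop2 = pops[j],
                                   fst = x$pairwise[i, j],
                                   p_value = x$p_values[i, j]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# global_fst\t%.6g", x$global_fst), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
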