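#' Allele-sharing relatedness between two individuals
#'
#' Per locus the score is half the size of the multiset intersection of the
#' two unordered allele pairs: identical genotypes score 1, sharing one allele
#' copy scores 0.5 (`AA` vs `AB`, `AB` vs `AC`), sharing none scores 0
#' (`AA` vs `BB`, `AB` vs `CD`). Bxy is the mean score over loci typed in both
#' individuals.
#'
#' @param x a `geno_data` object.
#' @param id1,id2 individual ids.
#' @return Bxy in `[0, 1]`; `NA` with a `"reason"` attribute when the pair
#'   shares no typed locus.
#' @export
bxy_pair <- function(x, id1, id2) {
  i <- match(id1, x$ids); j <- match(id2, x$ids)
  if (is.na(i) || is.na(j)) stop("unknown individual id")
  s <- locus_share_scores(x$a1[i, ], x$a2[i, ], x$a1[j, ], x$a2[j, ])
  if (all(is.na(s))) {
    out <- NA_real_
    attr(out, "reason") <- "no shared typed locus"
    return(out)
  }
  mean(s, na.rm = TRUE)
}

# per-locus allele-sharing scores for one pair (vectors over loci)
locus_share_scores <- function(a1, b1, a2, b2) {
  # multiset intersection of {a1,b1} and {a2,b2}, halved
  m <- mapply(function(p, q, r, s) {
    if (is.na(p) || is.na(r)) return(NA_real_)
    sum(pmin(tabulate(c(p, q), 50), tabulate(c(r, s), 50))) / 2
  }, a1, b1, a2, b2)
  as.numeric(m)
}

# Per-locus pairwise score matrices for all unordered individual pairs.
# Returns S (L x P score, NA when either individual untyped), T (L x P typed
# indicator) and the pair index. Scores use the identity
# |multiset intersection| = sum_a min(x_a, y_a) = (4 - sum_a |x_a - y_a|) / 2
# on per-allele copy counts, which vectorises over individuals.
bxy_locus_scores <- function(x) {
  n <- length(x$ids)
  if (n < 2) stop("need >= 2 individuals")
  pr <- utils::combn(n, 2)
  P <- ncol(pr)
  L <- nrow(x$loci)
  S <- matrix(NA_real_, L, P)
  ii <- pr[1, ]; jj <- pr[2, ]
  for (l in seq_len(L)) {
    k <- length(x$alleles[[l]])
    a1 <- x$a1[, l]; a2 <- x$a2[, l]
    d <- numeric(n * 0 + P)
    d[] <- 0
    for (v in seq_len(k)) {
      cv <- (a1 == v) + (a2 == v)
      d <- d + abs(cv[ii] - cv[jj])
    }
    S[l, ] <- 1 - d / 4                      # NA where either call missing
  }
  list(S = S, typed = !is.na(S), i = ii, j = jj,
       pair_ids = data.frame(id1 = x$ids[ii], id2 = x$ids[jj],
                             stringsAsFactors = FALSE))
}

#' Pairwise Bxy relatedness matrix
#'
#' @param x a `geno_data` object.
#' @param min_shared pairs typed together at fewer loci than this get `NA`
#'   rather than a noisy estimate.
#' @return a `relatedness_result`: list with the symmetric `bxy` matrix
#'   (diagonal 1 for individuals typed anywhere) and the matching
#'   `n_loci_used` matrix.
#' @export
bxy_matrix <- function(x, min_shared = 5) {
  sc <- bxy_locus_scores(x)
  n <- length(x$ids)
  num <- colSums(sc$S, na.rm = TRUE)
  den <- colSums(sc$typed)
  val <- ifelse(den >= min_shared, num / den, NA_real_)
  bxy <- matrix(NA_real_, n, n, dimnames = list(x$ids, x$ids))
  nl <- matrix(0L, n, n, dimnames = list(x$ids, x$ids))
  idx <- cbind(sc$i, sc$j)
  bxy[idx] <- val; bxy[idx[, 2:1]] <- val
  nl[idx] <- den; nl[idx[, 2:1]] <- den
  typed_any <- rowSums(!is.na(x$a1)) > 0
  diag(bxy) <- ifelse(typed_any, 1, NA)
  diag(nl) <- rowSums(!is.na(x$a1))
  structure(list(bxy = bxy, n_loci_used = nl, min_shared = min_shared),
            class = "relatedness_result")
}

#' @export
print.relatedness_result <- function(x, ...) {
  v <- x$bxy[upper.tri(x$bxy)]
  cat(sprintf("Bxy relatedness: %d individuals, %d pairs (%d NA)\n",
              nrow(x$bxy), length(v), sum(is.na(v))))
  cat(sprintf("  mean %.3f, range %.3f-%.3f\n", mean(v, na.rm = TRUE),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Precision of Bxy under random locus subsets
#'
#' For each subset size and replicate, a random subset of loci is drawn
#' (without replacement within a replicate by default; the bootstrap spread
#' comes from the replicate-level resampling), all pairwise Bxy values are
#' recomputed from the subset, and the mean over pairs of the absolute
#' difference from the full-panel Bxy is recorded. The curve of these means
#' against subset size measures how many loci a marker panel needs before
#' relatedness estimates stabilise.
#'
#' @param x a `geno_data` object.
#' @param subset_sizes integer vector of subset sizes (each `<=` number of
#'   loci).
#' @param n_replicates replicates per size.
#' @param seed integer seed.
#' @param replace sample loci with replacement within a replicate.
#' @param min_shared forwarded pair support threshold as in [bxy_matrix()].
#' @return a `subset_precision_curve`: `curve` (long data frame: subset_size,
#'   replicate, mean_abs_difference) and `summary` (per-size mean and sd).
#' @export
subset_precision <- function(x, subset_sizes, n_replicates = 1000, seed = 1,
                             replace = FALSE, min_shared = 1) {
  L <- nrow(x$loci)
  if (any(subset_sizes < 1)) stop("subset sizes must be >= 1")
  if (max(subset_sizes) > L) stop("subset size exceeds locus count")
  sc <- bxy_locus_scores(x)
  S0 <- sc$S; S0[is.na(S0)] <- 0
  Tm <- sc$typed * 1
  full_num <- colSums(S0); full_den <- colSums(Tm)
  full <- ifelse(full_den > 0, full_num / full_den, NA)
  set.seed(seed)
  out <- vector("list", length(subset_sizes))
  for (si in seq_along(subset_sizes)) {
    s <- subset_sizes[si]
    M <- matrix(0, n_replicates, L)
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(L, s, replace = replace)
      if (replace) {
        tb <- tabulate(idx, L); M[b, ] <- tb
      } else M[b, idx] <- 1
    }
    num <- M %*% S0
    den <- M %*% Tm
    bxy <- num / den
    bxy[den < min_shared | den == 0] <- NA
    mad <- rowMeans(abs(bxy - rep(full, each = n_replicates)), na.rm = TRUE)
    out[[si]] <- data.frame(subset_size = s, replicate = seq_len(n_replicates),
                            mean_abs_difference = mad)
  }
  curve <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(split(curve, curve$subset_size), function(d)
    data.frame(subset_size = d$subset_size[1],
               mean = mean(d$mean_abs_difference, na.rm = TRUE),
               sd = stats::sd(d$mean_abs_difference))))
  summ <- summ[order(summ$subset_size), ]
  rownames(summ) <- NULL
  structure(list(curve = curve, summary = summ, n_replicates = n_replicates,
                 seed = seed, replace = replace),
            class = "subset_precision_curve")
}

#' @export
print.subset_precision_curve <- function(x, ...) {
  cat("Bxy subset-precision curve (mean |Bxy_subset - Bxy_full| over pairs)\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write Bxy results as delimited text
#' @param x a `relatedness_result` or `subset_precision_curve`.
#' @param path output path.
#' @export
write_relatedness <- function(x, path) {
  if (inherits(x, "relatedness_result"))
    utils::write.table(x$bxy, path, sep = "\t", quote = FALSE, col.names = NA)
  else utils::write.table(x$curve, path, sep = "\t", quote = FALSE,
                          row.names = FALSE)
  invisible(path)
}
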