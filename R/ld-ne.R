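#' Mean Burrows composite r-squared between unlinked loci
#'
#' For every unordered locus pair the Burrows composite disequilibrium
#' `Delta-hat` is computed from unphased genotype counts -- the sample
#' covariance (n-1 denominator) of the per-individual allele-copy counts,
#' halved -- and converted to a squared correlation by dividing `Delta-hat^2`
#' by the product of the per-locus variance terms `p(1-p) + (P_hom - p^2)`,
#' which adjust the binomial variance for homozygote excess. Multiallelic loci
#' are decomposed into per-allele indicators (alleles with frequency inside
#' `[maf_cutoff, 1 - maf_cutoff]`) and the locus-pair r-squared is the mean
#' over allele-indicator combinations; biallelic loci contribute their minor
#' allele only (both indicators give the identical r-squared). Loci whose
#' minor allele frequency falls below `maf_cutoff` are excluded before
#' pairing. `r2_mean` is the unweighted mean over locus pairs.
#'
#' @param x a `geno_data` object.
#' @param population optional population label; default uses all individuals
#'   (they should form one population).
#' @param maf_cutoff minimum allele frequency screen (0.02 by convention).
#' @param min_overlap pairs whose complete-genotype overlap falls below this
#'   many individuals are skipped and counted.
#' @return list with `r2_mean`, `n_pairs`, `sample_size` (harmonic mean
#'   complete-pair sample size) and `n_skipped`.
#' @export
burrows_r2 <- function(x, population = NULL, maf_cutoff = 0.02,
                       min_overlap = 4) {
  if (!is.null(population)) x <- subset_populations(x, population)
  n <- length(x$ids)
  if (n < 10) warning("fewer than 10 individuals: LD-based Ne will be noisy")
  ex <- expand_alleles(x)
  cnt <- ex$counts
  p_all <- colMeans(cnt, na.rm = TRUE) / 2
  k_of <- table(ex$locus_of)[as.character(ex$locus_of)]
  keep <- p_all >= maf_cutoff & p_all <= 1 - maf_cutoff
  # biallelic loci: keep the minor allele column only
  bi_major <- as.vector(k_of) == 2 & ex$allele_of == which_major(ex, p_all)
  keep <- keep & !bi_major
  # drop zero-information columns (e.g. every individual heterozygous)
  vterm <- p_all * (1 - p_all) + colMeans(cnt == 2, na.rm = TRUE) - p_all^2
  keep <- keep & is.finite(vterm) & vterm > 1e-12
  keep[is.na(keep)] <- FALSE
  loci_kept <- unique(ex$locus_of[keep])
  if (length(loci_kept) < 2)
    stop("fewer than 2 polymorphic loci after the MAF screen")
  X <- cnt[, keep, drop = FALSE]
  f <- match(ex$locus_of[keep], loci_kept)            # column -> locus index

  # pairwise-complete statistics for every column pair via cross-products:
  # missing calls contribute zero to every sum and are excluded through the
  # typed-indicator counts, so each pair uses exactly its complete overlap
  Tm <- (!is.na(X)) * 1
  X0 <- X; X0[is.na(X0)] <- 0L
  H0 <- (X == 2L) * 1; H0[is.na(H0)] <- 0
  Nab <- crossprod(Tm)
  Sxy <- crossprod(X0)
  Sx <- crossprod(X0, Tm)                             # sum of x over overlap
  Sy <- t(Sx)
  Hx <- crossprod(H0, Tm); Hy <- t(Hx)
  px <- Sx / (2 * Nab); py <- Sy / (2 * Nab)
  cv <- (Sxy - Sx * Sy / Nab) / (Nab - 1)
  vx <- px * (1 - px) + Hx / Nab - px^2
  vy <- py * (1 - py) + Hy / Nab - py^2
  R2 <- pmin((cv / 2)^2 / (vx * vy), 1)   # cap at the theoretical maximum
  valid <- Nab >= min_overlap & is.finite(R2) & vx > 1e-12 & vy > 1e-12
  R2[!valid] <- 0
  Nv <- Nab * valid

  # aggregate allele-indicator pairs to locus pairs (unweighted over pairs)
  fl <- factor(f, levels = seq_along(loci_kept))
  agg <- function(M) rowsum(t(rowsum(M, fl)), fl)
  Snum <- agg(R2); Cnt <- agg(valid * 1); Ssz <- agg(Nv)
  ut <- upper.tri(Snum)
  ok <- Cnt[ut] > 0
  if (!any(ok)) stop("no usable locus pairs")
  r2_pair <- Snum[ut][ok] / Cnt[ut][ok]
  n_pair <- Ssz[ut][ok] / Cnt[ut][ok]                 # mean overlap per pair
  list(r2_mean = mean(r2_pair), n_pairs = length(r2_pair),
       sample_size = length(n_pair) / sum(1 / n_pair),
       n_skipped = sum(!ok))
}

# index of the majority allele column within each biallelic locus
which_major <- function(ex, p_all) {
  out <- integer(length(p_all))
  for (l in unique(ex$locus_of)) {
    cols <- which(ex$locus_of == l)
    out[cols] <- ex$allele_of[cols[which.max(p_all[cols])]]
  }
  out
}

#' Expected sampling contribution to the composite r-squared
#'
#' Finite samples of unphased diploids produce non-zero composite r-squared
#' even between independent loci. The empirical expectation used by the
#' LD-based Ne literature is `1/S + 3.19/S^2` for `S >= 30` and
#' `0.0018 + 0.907/S + 4.44/S^2` for smaller samples.
#'
#' @param S sample size (individuals).
#' @return expected r-squared under no linkage disequilibrium.
#' @export
r2_sample_expectation <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

# closed-form Ne from drift r2; Inf when drift r2 <= 0 or the discriminant is
# negative
ne_from_drift <- function(r2_drift, S) {
  if (is.na(r2_drift)) return(NA_real_)
  if (r2_drift <= 0) return(Inf)
  if (S >= 30) { a <- 1 / 3; b <- 2.76 }
  else { a <- 0.308; b <- 2.08 }
  disc <- a^2 - b * r2_drift
  if (disc < 0) return(Inf)
  (a + sqrt(disc)) / (2 * r2_drift)
}

#' Effective population size from mean composite r-squared
#'
#' Subtracts the sampling expectation (`1/S` for `S >= 30`, else
#' `0.0018 + 0.907/S + 4.44/S^2`) from the mean r-squared and inverts the
#' drift relationship: `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')` for
#' `S >= 30`, with coefficients 0.308 / 0.308^2 / 2.08 for smaller samples.
#' A non-positive drift r-squared (or negative discriminant) yields `Inf`.
#'
#' @param r2_mean mean composite r-squared over locus pairs.
#' @param sample_size number of individuals S (>= 2).
#' @return list with `ne_raw`, `r2_drift`, `r2_sample_expect`.
#' @export
ne_from_r2 <- function(r2_mean, sample_size) {
  if (sample_size < 2) stop("sample_size must be >= 2")
  e <- r2_sample_expectation(sample_size)
  d <- r2_mean - e
  list(ne_raw = ne_from_drift(d, sample_size), r2_drift = d,
       r2_sample_expect = e)
}

#' Chromosome-number bias correction for LD-based Ne
#'
#' Physical linkage between loci on the same chromosome biases LD-based Ne
#' downward in species with few chromosomes. The correction divides the raw
#' estimate by `0.098 + 0.219 * ln(n_chromosomes)`; at a haploid chromosome
#' number of 40 the divisor is 0.906.
#'
#' @param ne_raw raw Ne estimate (may be `Inf`, which maps to `Inf`).
#' @param n_chromosomes haploid chromosome number (>= 2).
#' @return corrected Ne.
#' @export
chromosome_bias_correction <- function(ne_raw, n_chromosomes) {
  if (n_chromosomes < 2) stop("n_chromosomes must be >= 2")
  ne_raw / chromosome_bias_factor(n_chromosomes)
}

#' @rdname chromosome_bias_correction
#' @export
chromosome_bias_factor <- function(n_chromosomes) {
  if (n_chromosomes < 2) stop("n_chromosomes must be >= 2")
  0.098 + 0.219 * log(n_chromosomes)
}

#' Jackknife confidence interval for LD-based Ne
#'
#' Non-parametric jackknife over individuals: the mean r-squared is recomputed
#' leaving each individual out, the jackknife variance of the drift r-squared
#' is formed on that scale, and the normal-theory interval endpoints are then
#' transformed through the Ne closed form (the upper r-squared bound maps to
#' the lower Ne bound and vice versa). A non-positive lower r-squared bound
#' gives an infinite upper Ne bound.
#'
#' @param x a `geno_data` object.
#' @param population optional population label.
#' @param maf_cutoff MAF screen forwarded to [burrows_r2()].
#' @param confidence confidence level.
#' @return list with `ci_low`, `ci_high` (raw Ne scale), `se_r2` and
#'   `degenerate` (TRUE when all leave-one-out values coincide and the
#'   interval collapses to the point estimate).
#' @export
ne_jackknife_ci <- function(x, population = NULL, maf_cutoff = 0.02,
                            confidence = 0.95) {
  if (!is.null(population)) x <- subset_populations(x, population)
  n <- length(x$ids)
  if (n < 5) stop("jackknife needs >= 5 individuals")
  full <- burrows_r2(x, maf_cutoff = maf_cutoff)
  theta_full <- full$r2_mean - r2_sample_expectation(full$sample_size)
  theta <- vapply(seq_len(n), function(i) {
    b <- burrows_r2(x[-i, ], maf_cutoff = maf_cutoff)
    b$r2_mean - r2_sample_expectation(b$sample_size)
  }, numeric(1))
  v <- (n - 1) / n * sum((theta - mean(theta))^2)
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  r_lo <- theta_full - z * se
  r_hi <- theta_full + z * se
  degenerate <- se == 0
  list(ci_low = ne_from_drift(r_hi, full$sample_size),
       ci_high = if (r_lo <= 0) Inf else ne_from_drift(r_lo, full$sample_size),
       se_r2 = se, degenerate = degenerate)
}

#' LD-based effective population size for one population
#'
#' Full pipeline: MAF screen, Burrows composite r-squared over all locus
#' pairs, sample-size correction, point estimate, jackknife confidence
#' interval, and the chromosome-number bias correction. Both the raw and the
#' corrected estimates are reported.
#'
#' @param x a `geno_data` object.
#' @param population population label (default: the only population present).
#' @param maf_cutoff minimum allele frequency (0.02).
#' @param n_chromosomes haploid chromosome number for the bias correction
#'   (40 by default); `NA` skips the correction.
#' @param confidence jackknife confidence level.
#' @param ci logical; compute the jackknife interval.
#' @return an `ne_estimate` object.
#' @export
ld_ne <- function(x, population = NULL, maf_cutoff = 0.02, n_chromosomes = 40,
                  confidence = 0.95, ci = TRUE) {
  if (!is.null(population)) x <- subset_populations(x, population)
  b <- burrows_r2(x, maf_cutoff = maf_cutoff)
  pt <- ne_from_r2(b$r2_mean, b$sample_size)
  fac <- if (is.na(n_chromosomes)) 1 else chromosome_bias_factor(n_chromosomes)
  jk <- if (ci) ne_jackknife_ci(x, maf_cutoff = maf_cutoff,
                                confidence = confidence)
        else list(ci_low = NA_real_, ci_high = NA_real_, degenerate = NA)
  structure(list(r2_mean = b$r2_mean, r2_sample_expect = pt$r2_sample_expect,
                 r2_drift = pt$r2_drift, ne_raw = pt$ne_raw,
                 ne_corrected = pt$ne_raw / fac,
                 ci_low = jk$ci_low, ci_high = jk$ci_high,
                 ci_low_corrected = jk$ci_low / fac,
                 ci_high_corrected = jk$ci_high / fac,
                 degenerate_ci = jk$degenerate,
                 n_pairs = b$n_pairs, n_skipped = b$n_skipped,
                 sample_size = b$sample_size, maf_cutoff = maf_cutoff,
                 n_chromosomes = n_chromosomes, confidence = confidence),
            class = "ne_estimate")
}

fmt_ne <- function(v, digits = 1) {
  ifelse(is.infinite(v), "infinite", formatC(v, format = "f", digits = digits))
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("LD-based Ne (S = %.1f, %d locus pairs, MAF >= %.3g)\n",
              x$sample_size, x$n_pairs, x$maf_cutoff))
  cat(sprintf("  raw:       %s (%s-%s)\n", fmt_ne(x$ne_raw),
              fmt_ne(x$ci_low), fmt_ne(x$ci_high)))
  if (!is.na(x$n_chromosomes))
    cat(sprintf("  corrected: %s (%s-%s)  [divisor %.3f, %d chromosomes]\n",
                fmt_ne(x$ne_corrected), fmt_ne(x$ci_low_corrected),
                fmt_ne(x$ci_high_corrected),
                chromosome_bias_factor(x$n_chromosomes), x$n_chromosomes))
  invisible(x)
}
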