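#' Filter-chain configuration
#'
#' Thresholds for the marker/individual quality-filter chain. Defaults follow
#' common RADseq practice for small population panels: loci must be present in
#' all populations and in at least 60% of individuals; individuals with more
#' than 20% missing data and markers with more than 30% missing data are
#' discarded (missingness comparisons are deliberately strict); markers with
#' observed heterozygosity above 0.5 are treated as assembly artefacts; the
#' MAF screen keeps markers with global MAF >= 0.005 that are also common
#' (MAF >= 0.02) in at least one population; and loci must be consistent with
#' Hardy--Weinberg equilibrium (p > 0.05) in at least two populations.
#'
#' @param min_populations_present populations a locus must be typed in
#'   (`NULL` = all populations in the dataset).
#' @param min_individual_fraction fraction of individuals a locus must be
#'   typed in.
#' @param max_individual_missing individuals above this missing fraction are
#'   dropped (strict `>`).
#' @param max_marker_missing markers above this missing fraction are dropped
#'   (strict `>`).
#' @param max_marker_het maximum observed marker heterozygosity.
#' @param maf_local,maf_global minor allele frequency screens (multiallelic
#'   MAF is `1 -` the major allele frequency).
#' @param hwe_alpha,hwe_min_pops a locus is retained when its HWE p-value
#'   exceeds `hwe_alpha` in at least `hwe_min_pops` populations (a population
#'   where the locus is monomorphic cannot reject and counts as consistent).
#' @param hwe_method,hwe_n_permutations,hwe_seed HWE test settings; the fixed
#'   seed makes the Monte-Carlo chain reproducible.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_populations_present = NULL,
                          min_individual_fraction = 0.60,
                          max_individual_missing = 0.20,
                          max_marker_missing = 0.30,
                          max_marker_het = 0.5,
                          maf_local = 0.02,
                          maf_global = 0.005,
                          hwe_alpha = 0.05,
                          hwe_min_pops = 2,
                          hwe_method = "mc_exact",
                          hwe_n_permutations = 1000,
                          hwe_seed = 1) {
  cfg <- list(min_populations_present = min_populations_present,
              min_individual_fraction = min_individual_fraction,
              max_individual_missing = max_individual_missing,
              max_marker_missing = max_marker_missing,
              max_marker_het = max_marker_het,
              maf_local = maf_local, maf_global = maf_global,
              hwe_alpha = hwe_alpha, hwe_min_pops = hwe_min_pops,
              hwe_method = hwe_method,
              hwe_n_permutations = hwe_n_permutations, hwe_seed = hwe_seed)
  fr <- c("min_individual_fraction", "max_individual_missing",
          "max_marker_missing", "max_marker_het", "maf_local", "maf_global",
          "hwe_alpha")
  for (nm in fr) if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
    stop(nm, " must lie in [0, 1]")
  structure(cfg, class = "filter_config")
}

#' Apply the marker/individual filter chain
#'
#' Filters run in a fixed order: (1) locus presence across populations and
#' individuals; (2) drop individuals with excess missing data; (3) drop
#' markers with excess missing data; (4) drop markers with excess observed
#' heterozygosity; then monomorphic loci are removed with their own report
#' line; (5) the minor-allele-frequency screen; (6) Hardy--Weinberg retention.
#' Because individual- and marker-level metrics feed back on each other (for
#' example, dropping markers changes individual missing fractions), a single
#' pass is not self-consistent; the chain is therefore iterated until a pass
#' removes nothing. This makes it exactly idempotent. The report accumulates
#' per-step removal counts over passes, and they reconcile with the input and
#' output dimensions.
#'
#' @param x a `geno_data` with >= 2 populations.
#' @param config a [filter_config()].
#' @return list with `data` (filtered `geno_data`) and `report` (a
#'   `filter_report` data frame: per-step removal counts and remaining
#'   dimensions), plus `n_passes`.
#' @export
apply_filter_chain <- function(x, config = filter_config()) {
  if (length(unique(x$pops)) < 2) stop("filter chain needs >= 2 populations")
  step_names <- c("locus_presence", "individual_missing", "marker_missing",
                  "marker_het", "monomorphic", "maf", "hwe")
  tot_l <- stats::setNames(integer(7), step_names)
  tot_i <- tot_l
  passes <- 0L
  repeat {
    before <- c(n_loci(x), n_individuals(x))
    ps <- filter_pass(x, config)
    x <- ps$data
    tot_l <- tot_l + ps$loci_removed
    tot_i <- tot_i + ps$ind_removed
    passes <- passes + 1L
    if (all(c(n_loci(x), n_individuals(x)) == before) || passes >= 20L) break
  }
  report <- data.frame(step = step_names, loci_removed = unname(tot_l),
                       individuals_removed = unname(tot_i),
                       stringsAsFactors = FALSE)
  report$loci_remaining <- n_loci(x)
  report$individuals_remaining <- n_individuals(x)
  class(report) <- c("filter_report", "data.frame")
  list(data = x, report = report, n_passes = passes)
}

# one pass of the chain in the fixed step order
filter_pass <- function(x, config) {
  lrm <- stats::setNames(integer(7),
                         c("locus_presence", "individual_missing",
                           "marker_missing", "marker_het", "monomorphic",
                           "maf", "hwe"))
  irm <- lrm
  note <- function(step, l0, i0, x) {
    lrm[step] <<- lrm[step] + l0 - n_loci(x)
    irm[step] <<- irm[step] + i0 - n_individuals(x)
    if (n_loci(x) == 0 || n_individuals(x) == 0)
      stop(sprintf("all data filtered out at step '%s'", step))
    x
  }
  minpop <- config$min_populations_present
  if (is.null(minpop)) minpop <- length(unique(x$pops))

  # (1) locus presence across populations and individuals
  l0 <- n_loci(x); i0 <- n_individuals(x)
  typed <- !is.na(x$a1)
  pops_present <- rowsum((typed) * 1, x$pops) > 0
  keep <- colSums(pops_present) >= minpop &
    colMeans(typed) >= config$min_individual_fraction
  x <- note("locus_presence", l0, i0, x[, keep])

  # (2) individuals with more than max_individual_missing missing data
  l0 <- n_loci(x); i0 <- n_individuals(x)
  imiss <- rowMeans(is.na(x$a1))
  x <- note("individual_missing", l0, i0, x[imiss <= config$max_individual_missing, ])

  # (3) markers with more than max_marker_missing missing data
  l0 <- n_loci(x); i0 <- n_individuals(x)
  lmiss <- colMeans(is.na(x$a1))
  x <- note("marker_missing", l0, i0, x[, lmiss <= config$max_marker_missing])

  # (4) marker heterozygosity cap
  l0 <- n_loci(x); i0 <- n_individuals(x)
  ho <- observed_het(x)
  x <- note("marker_het", l0, i0, x[, is.na(ho) | ho <= config$max_marker_het])

  # monomorphic loci carry no information and break the MAF logic
  l0 <- n_loci(x); i0 <- n_individuals(x)
  nall <- marker_allele_counts(x)
  x <- note("monomorphic", l0, i0, x[, nall >= 2])

  # (5) MAF screen: common somewhere, not vanishingly rare overall
  l0 <- n_loci(x); i0 <- n_individuals(x)
  gmaf <- marker_maf(x)
  lmaf <- marker_maf_by_pop(x)
  keep <- gmaf >= config$maf_global &
    apply(lmaf, 1, max, na.rm = TRUE) >= config$maf_local
  x <- note("maf", l0, i0, x[, keep])

  # (6) HWE retention in >= hwe_min_pops populations
  l0 <- n_loci(x); i0 <- n_individuals(x)
  pops <- unique(x$pops)
  pass <- matrix(FALSE, n_loci(x), length(pops))
  for (pi in seq_along(pops)) for (l in seq_len(n_loci(x))) {
    hw <- hwe_test(x, l, method = config$hwe_method,
                   n_permutations = config$hwe_n_permutations,
                   seed = config$hwe_seed, pop = pops[pi])
    pass[l, pi] <- is.na(hw$p_value) || hw$p_value > config$hwe_alpha
  }
  x <- note("hwe", l0, i0, x[, rowSums(pass) >= config$hwe_min_pops])

  list(data = x, loci_removed = lrm, ind_removed = irm)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter-chain report\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a filter report as delimited text
#' @param x a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# observed distinct alleles per marker
marker_allele_counts <- function(x) {
  vapply(seq_len(nrow(x$loci)), function(l)
    length(unique(c(x$a1[, l], x$a2[, l])[!is.na(c(x$a1[, l], x$a2[, l]))])),
    integer(1))
}

# global minor allele frequency per marker (1 - major frequency)
marker_maf <- function(x, rows = seq_along(x$ids)) {
  vapply(seq_len(nrow(x$loci)), function(l) {
    v <- c(x$a1[rows, l], x$a2[rows, l])
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    1 - max(tabulate(v, length(x$alleles[[l]]))) / length(v)
  }, numeric(1))
}

# per-population minor allele frequency matrix (loci x populations)
marker_maf_by_pop <- function(x) {
  pops <- unique(x$pops)
  out <- sapply(pops, function(p) marker_maf(x, which(x$pops == p)))
  matrix(out, nrow = nrow(x$loci), dimnames = list(x$loci$locus_id, pops))
}
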