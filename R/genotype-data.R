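#' Construct a diploid genotype dataset
#'
#' The `geno_data` container holds unphased diploid genotype calls for a set of
#' individuals at a set of loci, together with population labels and per-locus
#' marker metadata. Genotypes are stored as two parallel integer matrices of
#' allele indices (individuals x loci); the pair is unordered, so calls are
#' normalised to `a1 <= a2` on construction. A missing call is `NA` in both
#' matrices -- missingness is a distinct state, never a pseudo-allele.
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele indices into
#'   `alleles`, `NA` for missing calls. `a1[i,l]` and `a2[i,l]` must be both
#'   `NA` or both observed.
#' @param ids character vector of individual identifiers (unique).
#' @param pops character vector assigning each individual to a population.
#' @param loci data frame with columns `locus_id`, `marker_class`
#'   (`"microsatellite"` or `"SNP"`) and optionally `chromosome`.
#' @param alleles list (one element per locus) of character vectors of allele
#'   labels; SNP loci must have exactly two labels.
#' @return An object of class `geno_data`.
#' @export
genotype_dataset <- function(a1, a2, ids, pops, loci, alleles) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(ids)
  if (nrow(a1) != n || nrow(a2) != n)
    stop("genotype matrices must have one row per individual")
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (length(pops) != n) stop("one population label per individual required")
  if (!all(c("locus_id", "marker_class") %in% names(loci)))
    stop("loci must have columns locus_id and marker_class")
  if (is.null(loci$chromosome)) loci$chromosome <- NA_character_
  loci <- data.frame(locus_id = as.character(loci$locus_id),
                     marker_class = as.character(loci$marker_class),
                     chromosome = as.character(loci$chromosome),
                     stringsAsFactors = FALSE)
  L <- nrow(loci)
  if (ncol(a1) != L || ncol(a2) != L)
    stop("genotype matrices must have one column per locus")
  if (length(alleles) != L) stop("alleles must have one entry per locus")
  if (!all(loci$marker_class %in% c("microsatellite", "SNP")))
    stop("marker_class must be 'microsatellite' or 'SNP'")
  nall <- vapply(alleles, length, integer(1))
  if (any(loci$marker_class == "SNP" & nall != 2L))
    stop("SNP loci must have exactly 2 allele labels")
  if (any(vapply(alleles, anyDuplicated, integer(1)) > 0L))
    stop("allele labels must be unique within a locus")
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing calls are not allowed: a1 and a2 must share NA pattern")
  for (l in seq_len(L)) {
    v <- c(a1[, l], a2[, l])
    bad <- !is.na(v) & (v < 1L | v > nall[l])
    if (any(bad)) stop(sprintf("allele index out of range at locus %s", loci$locus_id[l]))
  }
  # unordered calls: normalise so a1 <= a2
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci$locus_id)
  names(alleles) <- loci$locus_id
  structure(list(ids = as.character(ids), pops = as.character(pops),
                 loci = loci, alleles = alleles, a1 = a1, a2 = a2),
            class = "geno_data")
}

#' @export
print.geno_data <- function(x, ...) {
  cls <- table(x$loci$marker_class)
  cat(sprintf("geno_data: %d individuals, %d loci (%s)\n",
              length(x$ids), nrow(x$loci),
              paste(sprintf("%d %s", cls, names(cls)), collapse = ", ")))
  pt <- table(x$pops)
  cat("populations:", paste(sprintf("%s (n=%d)", names(pt), pt), collapse = ", "), "\n")
  cat(sprintf("missing calls: %.2f%%\n", 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
summary.geno_data <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Number of individuals / loci
#' @param x a `geno_data` object.
#' @return integer count.
#' @export
n_individuals <- function(x) length(x$ids)

#' @rdname n_individuals
#' @export
n_loci <- function(x) nrow(x$loci)

#' Subset a genotype dataset
#'
#' `x[i, j]` keeps individuals `i` and loci `j`. Indices may be logical,
#' integer, or character (individual ids / locus ids). Allele label sets are
#' carried along unchanged, so subsetting preserves call values.
#'
#' @param x a `geno_data` object.
#' @param i individual selector.
#' @param j locus selector.
#' @param ... ignored.
#' @export
`[.geno_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ids)
  if (missing(j)) j <- seq_len(nrow(x$loci))
  if (is.character(i)) i <- match(i, x$ids)
  if (is.character(j)) j <- match(j, x$loci$locus_id)
  if (anyNA(i)) stop("unknown individual id in subset")
  if (anyNA(j)) stop("unknown locus id in subset")
  genotype_dataset(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                   x$ids[i], x$pops[i], x$loci[j, , drop = FALSE],
                   x$alleles[j])
}

#' Restrict a dataset to one marker class
#' @param x a `geno_data` object.
#' @param marker_class `"microsatellite"` or `"SNP"`.
#' @return a `geno_data` with only the requested loci.
#' @export
subset_markers <- function(x, marker_class) {
  marker_class <- match.arg(marker_class, c("microsatellite", "SNP"))
  keep <- x$loci$marker_class == marker_class
  if (!any(keep)) stop("no loci of class ", marker_class)
  x[, keep]
}

#' Restrict a dataset to selected populations
#' @param x a `geno_data` object.
#' @param populations character vector of population labels to keep.
#' @export
subset_populations <- function(x, populations) {
  if (!all(populations %in% x$pops)) stop("unknown population label")
  x[x$pops %in% populations, ]
}

#' Genotype calls as allele-label strings
#'
#' Materialises the calls as `"label1/label2"` strings (labels sorted within
#' the call, `NA` for missing). Two datasets hold the same genotypes iff their
#' label matrices are identical, regardless of internal allele index order --
#' the natural invariant for format round-trips.
#'
#' @param x a `geno_data` object.
#' @return character matrix (individuals x loci).
#' @export
genotype_labels <- function(x) {
  out <- matrix(NA_character_, length(x$ids), nrow(x$loci),
                dimnames = list(x$ids, x$loci$locus_id))
  for (l in seq_len(nrow(x$loci))) {
    lab <- x$alleles[[l]]
    ok <- !is.na(x$a1[, l])
    l1 <- lab[x$a1[ok, l]]; l2 <- lab[x$a2[ok, l]]
    out[ok, l] <- paste(pmin(l1, l2), pmax(l1, l2), sep = "/")
  }
  out
}

# ---- internal helpers shared by the statistics modules ---------------------

# Per-allele gene-copy indicator expansion: an individuals x M matrix where
# column m counts copies (0/1/2, NA if the call is missing) of allele
# allele_of[m] at locus locus_of[m]. This is the workhorse representation for
# F_ST, LD and diversity computations.
expand_alleles <- function(x, loci = seq_len(nrow(x$loci))) {
  if (is.character(loci)) loci <- match(loci, x$loci$locus_id)
  k <- vapply(x$alleles[loci], length, integer(1))
  M <- sum(k)
  n <- length(x$ids)
  counts <- matrix(NA_integer_, n, M)
  locus_of <- rep(loci, k)
  allele_of <- unlist(lapply(k, seq_len), use.names = FALSE)
  maxk <- max(k)
  a1 <- x$a1[, loci, drop = FALSE]
  a2 <- x$a2[, loci, drop = FALSE]
  col_of <- split(seq_len(M), rep(seq_along(loci), k))
  for (v in seq_len(maxk)) {
    cnt <- (a1 == v) + (a2 == v)          # NA propagates for missing calls
    sel <- which(k >= v)                   # loci having an allele index v
    cols <- vapply(sel, function(j) col_of[[j]][v], integer(1))
    counts[, cols] <- cnt[, sel, drop = FALSE]
  }
  colnames(counts) <- paste(x$loci$locus_id[locus_of], allele_of, sep = ".")
  list(counts = counts, locus_of = locus_of, allele_of = allele_of)
}

# Gene-copy counts per population: list with
#   copies  : L x npop matrix of allele-column sums aggregated to loci (2 x typed)
#   acounts : M x npop matrix of per-allele gene-copy counts
#   locus_of: column -> locus map
pop_allele_counts <- function(x, loci = seq_len(nrow(x$loci))) {
  ex <- expand_alleles(x, loci)
  pops <- factor(x$pops, levels = unique(x$pops))
  # rowsum over individuals grouped by population, NA (missing) removed
  ac <- rowsum(ex$counts, pops, na.rm = TRUE)      # npop x M
  acounts <- t(ac)
  lidx <- factor(ex$locus_of, levels = unique(ex$locus_of))
  copies <- rowsum(acounts, lidx)                  # L x npop total gene copies
  list(acounts = acounts, copies = copies, locus_of = ex$locus_of,
       allele_of = ex$allele_of, pop_levels = levels(pops),
       locus_levels = unique(ex$locus_of))
}

# observed heterozygosity per locus over a set of rows
observed_het <- function(x, rows = seq_along(x$ids)) {
  het <- x$a1[rows, , drop = FALSE] != x$a2[rows, , drop = FALSE]
  colMeans(het, na.rm = TRUE)
}

# logical heterozygosity matrix (NA where missing)
het_matrix <- function(x) x$a1 != x$a2
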