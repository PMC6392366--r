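#' Read a Genepop file
#'
#' Parses the classic Genepop dialect: a title line, one locus name per line
#' (or a single comma-separated line), `POP` separators, and individual lines
#' of the form `id ,  aaabbb aaabbb ...` with 2- or 3-digit allele codes.
#' The code width is auto-detected per file; `000000` / `0000` (or an all-zero
#' half) denotes a missing call. Allele labels are the numeric codes as
#' strings.
#'
#' @param path path to the Genepop file.
#' @param pop_names optional character vector of population names, one per
#'   `POP` block; defaults to `pop_1`, `pop_2`, ...
#' @param marker_class marker class recorded for all loci (Genepop files in
#'   this pipeline carry microsatellites).
#' @return a [genotype_dataset()] object.
#' @export
read_genepop <- function(path, pop_names = NULL, marker_class = "microsatellite") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  body <- lines[-1]                                    # drop title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no POP separator")
  locus_lines <- body[seq_len(first_pop - 1)]
  loci_names <- trimws(unlist(strsplit(locus_lines, ",")))
  loci_names <- loci_names[nzchar(loci_names)]
  L <- length(loci_names)
  if (L == 0) stop("no locus names before first POP")

  ids <- character(); pops <- character(); rows <- list()
  width <- NA_integer_
  pop_i <- 0L
  for (k in seq(first_pop, length(body))) {
    ln <- body[k]
    if (is_pop[k]) { pop_i <- pop_i + 1L; next }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop(sprintf("line %d: expected 'id , genotypes'", k + 1L))
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(gts) != L)
      stop(sprintf("line %d: %d genotypes found, %d loci declared",
                   k + 1L, length(gts), L))
    w <- unique(nchar(gts))
    if (length(w) != 1 || !(w %in% c(4L, 6L)))
      stop(sprintf("line %d: inconsistent genotype code widths", k + 1L))
    w <- w / 2L
    if (is.na(width)) width <- w
    if (w != width)
      stop(sprintf("line %d: mixed %d- and %d-digit allele codes", k + 1L, width, w))
    ids <- c(ids, id); pops <- c(pops, pop_i)
    rows[[length(rows) + 1L]] <- gts
  }
  if (length(rows) == 0) stop("no individuals found")
  npop <- pop_i
  if (is.null(pop_names)) pop_names <- paste0("pop_", seq_len(npop))
  if (length(pop_names) != npop) stop("pop_names must match number of POP blocks")

  g <- do.call(rbind, rows)
  half1 <- substr(g, 1L, width)
  half2 <- substr(g, width + 1L, 2L * width)
  zero <- strrep("0", width)
  half1[half1 == zero | half2 == zero] <- NA
  half2[is.na(half1)] <- NA
  dim(half1) <- dim(half2) <- dim(g)

  alleles <- vector("list", L)
  a1 <- matrix(NA_integer_, nrow(g), L)
  a2 <- matrix(NA_integer_, nrow(g), L)
  for (l in seq_len(L)) {
    lab <- sort(unique(c(half1[, l], half2[, l])))
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0) lab <- strrep("0", width) # fully missing locus
    alleles[[l]] <- lab
    a1[, l] <- match(half1[, l], lab)
    a2[, l] <- match(half2[, l], lab)
  }
  loci <- data.frame(locus_id = loci_names, marker_class = marker_class,
                     stringsAsFactors = FALSE)
  genotype_dataset(a1, a2, ids, pop_names[as.integer(pops)], loci, alleles)
}

#' Write a Genepop file
#'
#' Writes the 3-digit dialect by default (microsatellite allele sizes exceed
#' 99). Individuals are grouped into `POP` blocks by population, in first
#' appearance order; a missing call is written as all zeros. Allele labels
#' must be numeric strings within the code width.
#'
#' @param x a `geno_data` object.
#' @param path output path.
#' @param digits allele code width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, digits = 3) {
  if (!digits %in% c(2, 3)) stop("digits must be 2 or 3")
  labs <- lapply(x$alleles, function(a) {
    v <- suppressWarnings(as.integer(a))
    if (anyNA(v)) stop("Genepop output needs numeric allele labels")
    if (any(v >= 10^digits)) stop("allele label exceeds code width")
    sprintf(paste0("%0", digits, "d"), v)
  })
  L <- nrow(x$loci)
  code <- matrix(strrep("0", 2 * digits), length(x$ids), L)
  for (l in seq_len(L)) {
    ok <- !is.na(x$a1[, l])
    code[ok, l] <- paste0(labs[[l]][x$a1[ok, l]], labs[[l]][x$a2[ok, l]])
  }
  out <- c("markercmp genotype export", x$loci$locus_id)
  for (p in unique(x$pops)) {
    out <- c(out, "POP")
    for (i in which(x$pops == p))
      out <- c(out, paste(x$ids[i], ",", paste(code[i, ], collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a two-column population map
#'
#' Whitespace- or tab-delimited text with individual id in column 1 and
#' population label in column 2; no header.
#'
#' @param path file path.
#' @return named character vector (names = individual ids).
#' @export
read_pop_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "pop"))
  stats::setNames(as.character(tab$pop), as.character(tab$id))
}

#' Write a population map
#' @param x a `geno_data` object.
#' @param path output path.
#' @export
write_pop_map <- function(x, path) {
  utils::write.table(data.frame(id = x$ids, pop = x$pops),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read biallelic SNPs from a VCF file
#'
#' Uses `vcfR` for parsing. Only biallelic records are kept; multiallelic
#' records are skipped with a warning and counted in the `skipped_multiallelic`
#' attribute. Phased and unphased GT values are treated identically (calls are
#' unordered), `./.` becomes a missing call. VCF carries no population labels,
#' so these come from a sidecar map (see [read_pop_map()]); individuals absent
#' from the map get population `"unknown"`.
#'
#' @param path VCF path (plain or gzipped).
#' @param pop_map named character vector mapping individual id to population,
#'   or a path to a two-column map file.
#' @return a `geno_data` object with `marker_class = "SNP"`.
#' @export
read_vcf <- function(path, pop_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0) stop("VCF contains no records")
  if (!"FORMAT" %in% colnames(v@gt)) stop("VCF has no FORMAT column")
  if (!all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])))
    stop("missing GT format key")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  nskip <- sum(multi)
  if (nskip > 0)
    warning(sprintf("skipped %d multiallelic record(s)", nskip))
  keep <- which(!multi)
  if (length(keep) == 0) stop("no biallelic records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- colnames(gt)
  # split GT on / or |
  a1 <- sub("^([^/|]*)[/|].*$", "\\1", gt)
  a2 <- sub("^[^/|]*[/|](.*)$", "\\1", gt)
  a1[a1 == "." | a1 == ""] <- NA; a2[a2 == "." | a2 == ""] <- NA
  a1 <- matrix(as.integer(a1) + 1L, nrow(gt), ncol(gt))
  a2 <- matrix(as.integer(a2) + 1L, nrow(gt), ncol(gt))
  a1[is.na(a2)] <- NA; a2[is.na(a1)] <- NA
  locus_id <- fix[, "ID"]
  noid <- is.na(locus_id) | locus_id == "."
  locus_id[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  loci <- data.frame(locus_id = locus_id, marker_class = "SNP",
                     chromosome = fix[, "CHROM"], stringsAsFactors = FALSE)
  alleles <- Map(c, fix[, "REF"], fix[, "ALT"])
  if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map))
    pop_map <- read_pop_map(pop_map)
  pops <- if (is.null(pop_map)) rep("unknown", length(ids)) else {
    p <- unname(pop_map[ids]); p[is.na(p)] <- "unknown"; p
  }
  ds <- genotype_dataset(t(a1), t(a2), ids, pops, loci, alleles)
  attr(ds, "skipped_multiallelic") <- nskip
  ds
}

#' Write biallelic SNPs to a VCF file
#'
#' Minimal VCFv4.2 with a GT-only FORMAT. Records are emitted in locus order,
#' individuals in dataset order, so output is deterministic. A `.gz` suffix
#' triggers gzip compression.
#'
#' @param x a `geno_data` object; all loci must be biallelic.
#' @param path output path.
#' @export
write_vcf <- function(x, path) {
  k <- vapply(x$alleles, length, integer(1))
  if (any(k != 2)) stop("write_vcf requires biallelic loci")
  chrom <- x$loci$chromosome
  chrom[is.na(chrom)] <- "1"
  gt <- matrix("./.", nrow(x$loci), length(x$ids))
  for (l in seq_len(nrow(x$loci))) {
    ok <- !is.na(x$a1[, l])
    gt[l, ok] <- paste0(x$a1[ok, l] - 1L, "/", x$a2[ok, l] - 1L)
  }
  ref <- vapply(x$alleles, `[`, character(1), 1)
  alt <- vapply(x$alleles, `[`, character(1), 2)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=markercmp",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$ids), collapse = "\t"))
  rows <- paste(chrom, seq_len(nrow(x$loci)), x$loci$locus_id, ref, alt,
                ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}
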