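# Fixture builders and independent brute-force oracles shared by the suite.

# build a geno_data from a character matrix of "a/b" calls (NA = missing)
geno_from_labels <- function(calls, pops, marker_class = NULL, ids = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); L <- ncol(calls)
  if (is.null(ids)) ids <- sprintf("ind_%02d", seq_len(n))
  alleles <- lapply(seq_len(L), function(l) {
    v <- unlist(strsplit(calls[, l], "/", fixed = TRUE))
    sort(unique(v[!is.na(v)]))
  })
  if (is.null(marker_class))
    marker_class <- ifelse(vapply(alleles, length, 1L) <= 2, "SNP",
                           "microsatellite")
  a1 <- matrix(NA_integer_, n, L); a2 <- a1
  for (l in seq_len(L)) {
    parts <- strsplit(calls[, l], "/", fixed = TRUE)
    ok <- !is.na(calls[, l])
    a1[ok, l] <- match(vapply(parts[ok], `[`, "", 1), alleles[[l]])
    a2[ok, l] <- match(vapply(parts[ok], `[`, "", 2), alleles[[l]])
  }
  genotype_dataset(a1, a2, ids, pops,
                   data.frame(locus_id = sprintf("L%02d", seq_len(L)),
                              marker_class = marker_class,
                              stringsAsFactors = FALSE),
                   alleles)
}

# random small dataset for oracle comparisons
random_geno <- function(n, loci_k, seed, miss = 0, pops = rep("p", n)) {
  set.seed(seed)
  L <- length(loci_k)
  a1 <- matrix(NA_integer_, n, L); a2 <- a1
  for (l in seq_len(L)) {
    g <- rgamma(loci_k[l], 1); p <- g / sum(g)
    a1[, l] <- sample.int(loci_k[l], n, TRUE, p)
    a2[, l] <- sample.int(loci_k[l], n, TRUE, p)
  }
  if (miss > 0) {
    drop <- matrix(runif(n * L) < miss, n, L)
    a1[drop] <- NA; a2[drop] <- NA
  }
  genotype_dataset(a1, a2, sprintf("i%02d", seq_len(n)), pops,
                   data.frame(locus_id = sprintf("L%02d", seq_len(L)),
                              marker_class = ifelse(loci_k <= 2, "SNP",
                                                    "microsatellite"),
                              stringsAsFactors = FALSE),
                   lapply(loci_k, function(k) as.character(seq_len(k))))
}

# brute-force Bxy for one pair: explicit multiset intersection with table()
oracle_bxy <- function(x, id1, id2) {
  i <- match(id1, x$ids); j <- match(id2, x$ids)
  scores <- c()
  for (l in seq_len(n_loci(x))) {
    g1 <- c(x$a1[i, l], x$a2[i, l]); g2 <- c(x$a1[j, l], x$a2[j, l])
    if (anyNA(g1) || anyNA(g2)) next
    shared <- 0
    g2pool <- g2
    for (a in g1) {
      hit <- match(a, g2pool)
      if (!is.na(hit)) { shared <- shared + 1; g2pool <- g2pool[-hit] }
    }
    scores <- c(scores, shared / 2)
  }
  if (!length(scores)) NA_real_ else mean(scores)
}

# brute-force Burrows composite r2 by explicit indicator-variable sums,
# averaged over allele-indicator combinations per locus pair (biallelic loci
# contribute their minor allele only), mirroring the estimator's contract
oracle_burrows_r2 <- function(x, maf_cutoff = 0.02) {
  n <- length(x$ids); L <- n_loci(x)
  cols <- list()      # per locus: list of indicator count vectors
  for (l in seq_len(L)) {
    k <- length(x$alleles[[l]])
    counts <- lapply(seq_len(k), function(v)
      (x$a1[, l] == v) + (x$a2[, l] == v))
    p <- vapply(counts, function(cv) mean(cv) / 2, 1)
    keep <- p >= maf_cutoff & p <= 1 - maf_cutoff
    if (k == 2 && any(keep)) keep <- seq_len(k) == which.min(p)
    vs <- vapply(counts, function(cv) {
      pp <- mean(cv) / 2
      pp * (1 - pp) + mean(cv == 2) - pp^2
    }, 1)
    keep <- keep & vs > 1e-12
    cols[[l]] <- counts[keep]
  }
  usable <- which(vapply(cols, length, 1L) > 0)
  r2s <- c()
  for (ii in seq_along(usable)) for (jj in seq_along(usable)) {
    if (jj <= ii) next
    li <- usable[ii]; lj <- usable[jj]
    vals <- c()
    for (cx in cols[[li]]) for (cy in cols[[lj]]) {
      sxy <- 0; sx <- 0; sy <- 0
      for (g in seq_len(n)) {
        sxy <- sxy + cx[g] * cy[g]; sx <- sx + cx[g]; sy <- sy + cy[g]
      }
      delta <- (sxy - sx * sy / n) / (n - 1) / 2
      px <- sx / (2 * n); py <- sy / (2 * n)
      vx <- px * (1 - px) + mean(cx == 2) - px^2
      vy <- py * (1 - py) + mean(cy == 2) - py^2
      vals <- c(vals, min(delta^2 / (vx * vy), 1))
    }
    r2s <- c(r2s, mean(vals))
  }
  mean(r2s)
}

# Mendelian consistency of an offspring call with recorded parent genotypes
mendel_consistent <- function(off, sire, dam) {
  # off, sire, dam: length-2 allele index vectors
  (off[1] %in% sire && off[2] %in% dam) || (off[2] %in% sire && off[1] %in% dam)
}

# the toy 5-locus filter fixture: 2 populations x 10 individuals; locus 1 has
# 40% missing calls, locus 2 fails the global MAF screen, locus 3 has observed
# heterozygosity 0.8, loci 4-5 are clean HW loci at p = 0.3
filter_toy_fixture <- function() {
  n <- 20
  gt <- function(spec) unlist(mapply(rep, names(spec), spec))
  # locus 4/5 pattern per population: 1 AA, 4 AB, 5 BB (p = 0.3, Ho = 0.4)
  clean <- rep(gt(c("A/A" = 1, "A/B" = 4, "B/B" = 5)), 2)
  l1 <- rep(gt(c("A/A" = 2, "A/B" = 4, "B/B" = 4)), 2)
  l1[c(1, 3, 5, 7, 12, 14, 16, 18)] <- NA           # 8/20 = 40% missing
  l2 <- rep(gt(c("A/A" = 10)), 2); l2[5] <- "A/B"   # one minor copy
  l3 <- rep(gt(c("A/B" = 8, "A/A" = 1, "B/B" = 1)), 2)  # Ho = 0.8
  geno_from_labels(cbind(l1, l2, l3, clean, clean),
                   pops = rep(c("p1", "p2"), each = 10),
                   marker_class = "SNP")
}

filter_toy_config <- function() {
  # thresholds scaled to the 20-individual fixture: one minor copy out of 40
  # (MAF 0.025) must fail the global screen
  filter_config(maf_global = 0.03, maf_local = 0.06,
                hwe_method = "mc_exact", hwe_n_permutations = 200,
                hwe_seed = 1)
}
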