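#' IBD coefficients of the standard relationship classes
#'
#' `(k0, k1, k2)` = probability that a pair shares 0, 1 or 2 alleles identical
#' by descent: unrelated (1, 0, 0), half sibs (1/2, 1/2, 0), full sibs
#' (1/4, 1/2, 1/4), parent--offspring (0, 1, 0).
#'
#' @return named list of numeric triples.
#' @export
ibd_coefficients <- function() {
  list(unrelated = c(1, 0, 0),
       halfsib = c(0.5, 0.5, 0),
       fullsib = c(0.25, 0.5, 0.25),
       parentoffspring = c(0, 1, 0))
}

#' Convert a per-allele error rate to the per-genotype scale
#'
#' The simulator corrupts allele copies independently at rate `e`; the
#' likelihood's error model replaces whole genotypes. A genotype with two
#' independently corrupted alleles is wrong with probability `1 - (1-e)^2`,
#' which is the matching rate to hand the classifier for data carrying
#' per-allele error.
#'
#' @param e per-allele error rate.
#' @return per-genotype error rate.
#' @export
allele_to_genotype_error <- function(e) 1 - (1 - e)^2

#' Relationship model: IBD mixture with genotyping error
#'
#' @param error_rate per-genotype error rate, either a scalar or a named
#'   vector with elements `SNP` and `microsatellite` (defaults to the
#'   marker-specific rates 0.05 and 0.0001). The error model replaces an
#'   observed genotype, with probability `error_rate`, by a random genotype
#'   drawn at Hardy--Weinberg proportions for the locus.
#' @param classes subset of relationship classes to consider.
#' @return a `relationship_model` list.
#' @export
relationship_model <- function(error_rate = c(SNP = 0.05, microsatellite = 1e-4),
                               classes = names(ibd_coefficients())) {
  k <- ibd_coefficients()
  classes <- match.arg(classes, names(k), several.ok = TRUE)
  stopifnot(all(vapply(k, sum, 1) == 1), k$parentoffspring[2] == 1,
            all(error_rate >= 0 & error_rate <= 1))
  structure(list(ibd = k[classes], error_rate = error_rate),
            class = "relationship_model")
}

# classes ordered from least to most related; likelihood ties break toward
# the earlier (less related) class
class_order <- c("unrelated", "halfsib", "parentoffspring", "fullsib")

# per-locus genotype-pair probabilities P(G1, G2 | m alleles IBD) for
# m = 0, 1, 2, vectorised over loci. a1 <= b1 and a2 <= b2 are the sorted
# allele indices of the two genotypes; f/off give the flattened frequency
# lookup (p of allele v at locus l is f[off[l] + v]).
pair_locus_probs <- function(a1, b1, a2, b2, f, off) {
  pa1 <- f[off + a1]; pb1 <- f[off + b1]
  pa2 <- f[off + a2]; pb2 <- f[off + b2]
  hw1 <- ifelse(a1 == b1, pa1^2, 2 * pa1 * pb1)
  hw2 <- ifelse(a2 == b2, pa2^2, 2 * pa2 * pb2)
  p0 <- hw1 * hw2
  p2 <- hw1 * (a1 == a2 & b1 == b2)
  # one shared allele: sum over distinct shared types s of
  # p_s * p_(other allele of G1) * p_(other allele of G2)
  t1 <- ifelse(a1 == a2 | a1 == b2,
               pa1 * pb1 * ifelse(a1 == a2, pb2, pa2), 0)
  t2 <- ifelse(b1 != a1 & (b1 == a2 | b1 == b2),
               pb1 * pa1 * ifelse(b1 == a2, pb2, pa2), 0)
  list(p0 = p0, p1 = t1 + t2, p2 = p2)
}

# allele frequency estimates per locus from a set of rows (population sample)
estimate_freqs <- function(x, rows = seq_along(x$ids)) {
  lapply(seq_len(nrow(x$loci)), function(l) {
    k <- length(x$alleles[[l]])
    cnt <- tabulate(c(x$a1[rows, l], x$a2[rows, l]), k)
    if (sum(cnt) == 0) rep(1 / k, k) else cnt / sum(cnt)
  })
}

#' Log-likelihood of a pair of genotypes under a relationship class
#'
#' Per locus `L = sum_m k_m P(G1, G2 | m alleles IBD)` with the genotype-pair
#' probabilities from the IBD decomposition and allele frequencies estimated
#' from the population sample (the focal pair included). Genotyping error is
#' folded in by mixing the class likelihood with the product of
#' Hardy--Weinberg genotype probabilities:
#' `L_obs = (1-e)^2 L + (1 - (1-e)^2) HW(G1) HW(G2)`. Log-likelihoods are
#' summed over loci typed in both individuals; a zero-probability
#' configuration at `e = 0` legally yields `-Inf` (the class is excluded).
#'
#' @param x a `geno_data` object.
#' @param id1,id2 individual ids.
#' @param class relationship class name.
#' @param model a [relationship_model()].
#' @param freqs optional list of per-locus allele frequency vectors; default:
#'   estimated from the population the pair belongs to.
#' @return scalar log-likelihood.
#' @export
pair_class_likelihood <- function(x, id1, id2, class,
                                  model = relationship_model(), freqs = NULL) {
  class <- match.arg(class, names(model$ibd))
  i <- match(id1, x$ids); j <- match(id2, x$ids)
  if (is.na(i) || is.na(j)) stop("unknown individual id")
  if (x$pops[i] != x$pops[j])
    stop("sibship likelihoods are a within-population analysis")
  if (is.null(freqs)) freqs <- estimate_freqs(x, which(x$pops == x$pops[i]))
  ll <- pair_loglik_all(x, i, j, model, freqs)
  ll[[class]]
}

# log-likelihood of one pair under every class in the model
pair_loglik_all <- function(x, i, j, model, freqs) {
  ok <- which(!is.na(x$a1[i, ]) & !is.na(x$a1[j, ]))
  if (!length(ok)) return(stats::setNames(rep(NA_real_, length(model$ibd)),
                                          names(model$ibd)))
  k_per <- vapply(freqs, length, integer(1))
  off <- cumsum(k_per) - k_per
  f <- unlist(freqs, use.names = FALSE)
  e <- locus_error_rates(x, model)[ok]
  pr <- pair_locus_probs(x$a1[i, ok], x$a2[i, ok], x$a1[j, ok], x$a2[j, ok],
                         f, off[ok])
  w <- (1 - e)^2
  vapply(model$ibd, function(k) {
    lik <- w * (k[1] * pr$p0 + k[2] * pr$p1 + k[3] * pr$p2) + (1 - w) * pr$p0
    sum(log(lik))
  }, numeric(1))
}

locus_error_rates <- function(x, model) {
  e <- model$error_rate
  if (length(e) == 1 && is.null(names(e))) rep(e, nrow(x$loci))
  else {
    if (!all(x$loci$marker_class %in% names(e)))
      stop("error_rate must name every marker class present")
    unname(e[x$loci$marker_class])
  }
}

#' Classify all within-population pairs and cluster full-sib families
#'
#' Every pair in the population is assigned the maximum-likelihood
#' relationship class, with an equal-prior class probability
#' `L_class / sum(L)`. Likelihood ties break toward the less related class.
#' Full-sib families are the connected components of the graph whose edges are
#' pairs assigned `fullsib` with probability at or above `fullsib_prob`.
#'
#' @param x a `geno_data` object.
#' @param population population label; pairs spanning populations are not
#'   classified (within-population analysis only).
#' @param model a [relationship_model()].
#' @param classes classes considered (default all four).
#' @param fullsib_prob probability threshold for family edges.
#' @return a `sibship_result`: `pairs` data frame (ids, per-class
#'   log-likelihoods, assigned class, probability), `families` (list of id
#'   vectors, size >= 2), and `family_table` (full-sib family and half-sib
#'   dyad counts with mean probabilities).
#' @export
classify_pairs <- function(x, population, model = relationship_model(),
                           classes = names(model$ibd), fullsib_prob = 0.95) {
  rows <- which(x$pops == population)
  if (length(rows) < 2) stop("population must contain >= 2 individuals")
  if (!all(classes %in% names(model$ibd))) stop("unknown class requested")
  model$ibd <- model$ibd[classes]
  xs <- x[rows, ]
  n_inf <- sum(colSums(!is.na(xs$a1)) > 0 &
                 apply(xs$a1, 2, function(v) length(unique(v[!is.na(v)]))) > 1)
  if (n_inf < 20)
    warning(sprintf("only %d informative loci: sibship classification unreliable", n_inf))
  freqs <- estimate_freqs(xs)
  pr <- utils::combn(length(xs$ids), 2)
  res <- vector("list", ncol(pr))
  ord <- intersect(class_order, names(model$ibd))
  for (p in seq_len(ncol(pr))) {
    ll <- pair_loglik_all(xs, pr[1, p], pr[2, p], model, freqs)
    ll <- ll[ord]                               # tie-break order
    if (!any(is.finite(ll))) {
      best <- NA_character_
      prob <- stats::setNames(rep(NA_real_, length(ll)), names(ll))
    } else {
      best <- names(ll)[which.max(ll)]
      prob <- exp(ll - max(ll[is.finite(ll)]))
      prob[!is.finite(ll)] <- 0
      prob <- prob / sum(prob)
    }
    out <- data.frame(id1 = xs$ids[pr[1, p]], id2 = xs$ids[pr[2, p]],
                      class = best,
                      probability = if (is.na(best)) NA_real_ else unname(prob[best]),
                      stringsAsFactors = FALSE)
    for (cl in ord) out[[paste0("ll_", cl)]] <- unname(ll[cl])
    res[[p]] <- out
  }
  pairs <- do.call(rbind, res)
  fs <- pairs[pairs$class == "fullsib" & pairs$probability >= fullsib_prob, ]
  g <- igraph::graph_from_data_frame(fs[, c("id1", "id2")], directed = FALSE,
                                     vertices = xs$ids)
  comp <- igraph::components(g)
  fam <- split(names(comp$membership), comp$membership)
  fam <- unname(fam[vapply(fam, length, 1L) >= 2])
  hs <- pairs[pairs$class == "halfsib", ]
  family_table <- data.frame(
    population = population,
    fullsib_families = length(fam),
    fullsib_mean_prob = if (nrow(fs)) mean(fs$probability) else NA_real_,
    halfsib_dyads = nrow(hs),
    halfsib_mean_prob = if (nrow(hs)) mean(hs$probability) else NA_real_,
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, families = fam, family_table = family_table,
                 population = population, fullsib_prob = fullsib_prob,
                 model = model),
            class = "sibship_result")
}

#' @export
print.sibship_result <- function(x, ...) {
  cat(sprintf("Pairwise sibship classification, population %s (pairwise method)\n",
              x$population))
  print(table(x$pairs$class))
  cat(sprintf("full-sib families (prob >= %.2f): %d\n",
              x$fullsib_prob, length(x$families)))
  invisible(x)
}

#' Write sibship results as delimited text
#' @param x a `sibship_result`.
#' @param path output path for the pair table; the family partition goes to
#'   `<path>.families.tsv`.
#' @export
write_sibship <- function(x, path) {
  utils::write.table(x$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fam <- data.frame(
    family = rep(seq_along(x$families), vapply(x$families, length, 1L)),
    id = unlist(x$families))
  utils::write.table(fam, paste0(path, ".families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
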