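#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the study conditions the package targets: four small populations of 30
#' diploid individuals, 16 multiallelic microsatellites with 3--18 alleles,
#' 2,000 biallelic SNPs, Balding--Nichols divergence spanning realized pairwise
#' F_ST of roughly 0.06--0.21, within-population full-sib and half-sib
#' families, per-allele genotyping error of 0.05 for SNPs and 0.0001 for
#' microsatellites, light missingness, and a haploid chromosome number of 40.
#'
#' @param n_populations number of populations.
#' @param n_individuals_per_pop integer vector of sampled individuals per
#'   population.
#' @param divergence_F per-population Balding--Nichols drift parameter in
#'   `[0, 1)`; `F = 0` means the population frequencies equal the ancestral
#'   frequencies exactly.
#' @param n_msat_loci,n_snp_loci locus counts for the two marker classes.
#' @param msat_allele_range integer pair: min and max alleles per
#'   microsatellite locus (within `[2, 50]`).
#' @param snp_maf_floor lower bound for the ancestral SNP minor allele
#'   frequency.
#' @param family_plan data frame with columns `population`, `relationship`
#'   (`"fullsib"` or `"halfsib"`) and `family_size` (>= 2). Family members are
#'   sampled individuals; their parents are unsampled founders. Half-sib
#'   families share the sire, with dams drawn independently.
#' @param error_rate_snp,error_rate_msat per-allele genotyping error rate per
#'   marker class (an erroneous allele is replaced by a uniform random
#'   alternative allele at that locus).
#' @param missing_rate_individual,missing_rate_locus MCAR missingness rates;
#'   a call is observed with probability
#'   `(1 - missing_rate_individual) * (1 - missing_rate_locus)`.
#' @param n_chromosomes haploid chromosome number used to tag loci (reporting
#'   only; loci are simulated unlinked).
#' @param seed integer seed; the seed fully determines the output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_populations = 4,
                       n_individuals_per_pop = rep(30, n_populations),
                       divergence_F = c(0.20, 0.14, 0.10, 0.06)[seq_len(n_populations)],
                       n_msat_loci = 16,
                       msat_allele_range = c(3, 18),
                       n_snp_loci = 2000,
                       snp_maf_floor = 0.05,
                       family_plan = default_family_plan(n_populations),
                       error_rate_snp = 0.05,
                       error_rate_msat = 1e-4,
                       missing_rate_individual = 0.02,
                       missing_rate_locus = 0.02,
                       n_chromosomes = 40,
                       seed = 1) {
  cfg <- list(n_populations = as.integer(n_populations),
              n_individuals_per_pop = as.integer(n_individuals_per_pop),
              divergence_F = as.numeric(divergence_F),
              n_msat_loci = as.integer(n_msat_loci),
              msat_allele_range = as.integer(msat_allele_range),
              n_snp_loci = as.integer(n_snp_loci),
              snp_maf_floor = as.numeric(snp_maf_floor),
              family_plan = family_plan,
              error_rate_snp = as.numeric(error_rate_snp),
              error_rate_msat = as.numeric(error_rate_msat),
              missing_rate_individual = as.numeric(missing_rate_individual),
              missing_rate_locus = as.numeric(missing_rate_locus),
              n_chromosomes = as.integer(n_chromosomes),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_family_plan <- function(n_populations) {
  data.frame(population = rep(paste0("pop_", seq_len(n_populations)), each = 2),
             relationship = rep(c("fullsib", "halfsib"), n_populations),
             family_size = rep(c(4L, 3L), n_populations),
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_populations >= 1,
            length(cfg$n_individuals_per_pop) == cfg$n_populations,
            all(cfg$n_individuals_per_pop >= 1),
            length(cfg$divergence_F) == cfg$n_populations)
  rates <- c(cfg$divergence_F, cfg$snp_maf_floor, cfg$error_rate_snp,
             cfg$error_rate_msat, cfg$missing_rate_individual,
             cfg$missing_rate_locus)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(cfg$divergence_F >= 1)) stop("divergence_F must lie in [0, 1)")
  if (cfg$msat_allele_range[1] < 2 || cfg$msat_allele_range[2] > 50 ||
      cfg$msat_allele_range[1] > cfg$msat_allele_range[2])
    stop("msat_allele_range must lie within [2, 50]")
  fp <- cfg$family_plan
  if (!is.null(fp) && nrow(fp) > 0) {
    if (!all(fp$relationship %in% c("fullsib", "halfsib")))
      stop("family relationship must be 'fullsib' or 'halfsib'")
    if (any(fp$family_size < 2)) stop("family sizes must be >= 2")
    pops <- paste0("pop_", seq_len(cfg$n_populations))
    if (!all(fp$population %in% pops))
      stop("family_plan references unknown population")
    tot <- tapply(fp$family_size, fp$population, sum)
    avail <- stats::setNames(cfg$n_individuals_per_pop, pops)
    if (any(tot > avail[names(tot)]))
      stop("family plan larger than population size")
  }
  invisible(cfg)
}

# Dirichlet draw via gamma variates; for k = 2 this is the Balding-Nichols beta
# with parameters p(1-F)/F and (1-p)(1-F)/F.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) return(alpha / sum(alpha))   # degenerate shape guard
  g / sum(g)
}

# per-allele genotyping error: with probability `rate` an allele copy is
# replaced by a uniform random alternative allele at the locus
apply_genotype_error <- function(a1, a2, n_alleles, rate) {
  if (rate <= 0) return(list(a1 = a1, a2 = a2))
  for (nm in c("a1", "a2")) {
    a <- get(nm)
    hit <- which(!is.na(a) & stats::runif(length(a)) < rate)
    if (length(hit)) {
      l <- ((hit - 1L) %/% nrow(a)) + 1L      # column (locus) index
      k <- n_alleles[l]
      shift <- 1L + floor(stats::runif(length(hit)) * (k - 1L))
      a[hit] <- as.integer((a[hit] - 1L + shift) %% k + 1L)
      assign(nm, a)
    }
  }
  list(a1 = a1, a2 = a2)
}

#' Simulate a structured two-marker genotype dataset with known pedigree
#'
#' Draws ancestral allele frequencies per locus (symmetric Dirichlet over k
#' alleles for microsatellites, uniform above the MAF floor for SNPs), derives
#' population frequencies from the Balding--Nichols model, samples founders at
#' Hardy--Weinberg proportions, produces family offspring by Mendelian
#' segregation from designated (unsampled) parents, and finally applies
#' marker-class genotyping error and MCAR missingness. The same seed gives
#' bit-identical output.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `data` (a `geno_data`) and `truth` (a
#'   `pedigree_truth`: pedigree with parent ids, parental genotypes, true
#'   per-population allele frequencies, and the configured drift parameters).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  npop <- config$n_populations
  pop_names <- paste0("pop_", seq_len(npop))
  Lm <- config$n_msat_loci; Ls <- config$n_snp_loci
  L <- Lm + Ls

  alleles <- vector("list", L)
  anc <- vector("list", L)
  marker_class <- c(rep("microsatellite", Lm), rep("SNP", Ls))
  for (l in seq_len(Lm)) {
    k <- sample(seq(config$msat_allele_range[1], config$msat_allele_range[2]), 1)
    alleles[[l]] <- as.character(100 + 2 * (seq_len(k) - 1))  # repeat unit 2
    anc[[l]] <- rdirichlet1(rep(1, k))
  }
  for (l in Lm + seq_len(Ls)) {
    alleles[[l]] <- sample(c("A", "C", "G", "T"), 2)
    p <- stats::runif(1, config$snp_maf_floor, 1 - config$snp_maf_floor)
    anc[[l]] <- c(p, 1 - p)
  }

  # divergence_F is calibrated to the expected pairwise Nei F_ST between two
  # populations with the same setting: pairwise F_ST measures divergence
  # relative to the pooled pair (not the unobserved ancestor), which halves
  # the ancestral drift signal, so the beta draw uses G = 2F/(1+F); then
  # (G/2)/(1 - G/2) = F.
  bn_drift <- 2 * config$divergence_F / (1 + config$divergence_F)
  true_freqs <- vector("list", L)
  for (l in seq_len(L)) {
    k <- length(alleles[[l]])
    m <- matrix(NA_real_, k, npop, dimnames = list(alleles[[l]], pop_names))
    for (j in seq_len(npop)) {
      Gj <- bn_drift[j]
      m[, j] <- if (Gj == 0) anc[[l]] else rdirichlet1(anc[[l]] * (1 - Gj) / Gj)
    }
    true_freqs[[l]] <- m
  }

  draw_hw <- function(n, popfreqs) {
    # n independent HW genotypes for every locus; returns a1/a2 index matrices
    a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) {
      p <- popfreqs[[l]]
      a1[, l] <- sample.int(length(p), n, replace = TRUE, prob = p)
      a2[, l] <- sample.int(length(p), n, replace = TRUE, prob = p)
    }
    list(a1 = a1, a2 = a2)
  }
  mendel <- function(pa, pidx, n) {
    # one gamete per offspring from parent row pidx (recycled to length n)
    if (length(pidx) == 1L) pidx <- rep(pidx, n)
    m1 <- pa$a1[pidx, , drop = FALSE]
    m2 <- pa$a2[pidx, , drop = FALSE]
    pick <- matrix(stats::runif(n * L) < 0.5, n, L)
    out <- ifelse(pick, m1, m2)
    storage.mode(out) <- "integer"
    out
  }

  ids <- character(); pops <- character()
  sire <- character(); dam <- character()
  a1 <- NULL; a2 <- NULL
  par_ids <- character(); par_pop <- character()
  pa1 <- NULL; pa2 <- NULL

  for (j in seq_len(npop)) {
    popfreqs <- lapply(true_freqs, function(m) m[, j])
    n_j <- config$n_individuals_per_pop[j]
    fp <- config$family_plan
    if (is.null(fp))
      fp <- data.frame(population = character(), relationship = character(),
                       family_size = integer(), stringsAsFactors = FALSE)
    fp <- fp[fp$population == pop_names[j], , drop = FALSE]
    n_fam_off <- if (nrow(fp)) sum(fp$family_size) else 0L
    n_founders <- n_j - n_fam_off
    idx <- 0L

    if (n_founders > 0) {
      g <- draw_hw(n_founders, popfreqs)
      a1 <- rbind(a1, g$a1); a2 <- rbind(a2, g$a2)
      new_ids <- sprintf("%s_ind_%02d", pop_names[j], idx + seq_len(n_founders))
      idx <- idx + n_founders
      ids <- c(ids, new_ids); pops <- c(pops, rep(pop_names[j], n_founders))
      sire <- c(sire, rep(NA_character_, n_founders))
      dam <- c(dam, rep(NA_character_, n_founders))
    }
    if (nrow(fp)) for (f in seq_len(nrow(fp))) {
      fs <- fp$family_size[f]
      if (fp$relationship[f] == "fullsib") {
        par <- draw_hw(2, popfreqs)
        s_id <- sprintf("%s_sire_f%d", pop_names[j], f)
        d_id <- sprintf("%s_dam_f%d", pop_names[j], f)
        off1 <- mendel(par, 1L, fs); off2 <- mendel(par, 2L, fs)
        off_sire <- rep(s_id, fs); off_dam <- rep(d_id, fs)
        par_ids <- c(par_ids, s_id, d_id)
        par_pop <- c(par_pop, rep(pop_names[j], 2))
        pa1 <- rbind(pa1, par$a1); pa2 <- rbind(pa2, par$a2)
      } else {                                  # halfsib: shared sire
        par <- draw_hw(1 + fs, popfreqs)        # sire + fs dams
        s_id <- sprintf("%s_sire_f%d", pop_names[j], f)
        d_id <- sprintf("%s_dam_f%d_%d", pop_names[j], f, seq_len(fs))
        off1 <- mendel(par, rep(1L, fs), fs)
        off2 <- mendel(par, 1L + seq_len(fs), fs)
        off_sire <- rep(s_id, fs); off_dam <- d_id
        par_ids <- c(par_ids, s_id, d_id)
        par_pop <- c(par_pop, rep(pop_names[j], 1 + fs))
        pa1 <- rbind(pa1, par$a1); pa2 <- rbind(pa2, par$a2)
      }
      a1 <- rbind(a1, off1); a2 <- rbind(a2, off2)
      new_ids <- sprintf("%s_ind_%02d", pop_names[j], idx + seq_len(fs))
      idx <- idx + fs
      ids <- c(ids, new_ids); pops <- c(pops, rep(pop_names[j], fs))
      sire <- c(sire, off_sire); dam <- c(dam, off_dam)
    }
  }

  # genotyping error per marker class, then MCAR missingness
  n_alleles <- vapply(alleles, length, integer(1))
  im <- seq_len(Lm); is <- Lm + seq_len(Ls)
  if (Lm > 0) {
    e <- apply_genotype_error(a1[, im, drop = FALSE], a2[, im, drop = FALSE],
                              n_alleles[im], config$error_rate_msat)
    a1[, im] <- e$a1; a2[, im] <- e$a2
  }
  if (Ls > 0) {
    e <- apply_genotype_error(a1[, is, drop = FALSE], a2[, is, drop = FALSE],
                              n_alleles[is], config$error_rate_snp)
    a1[, is] <- e$a1; a2[, is] <- e$a2
  }
  p_miss <- 1 - (1 - config$missing_rate_individual) * (1 - config$missing_rate_locus)
  if (p_miss > 0) {
    drop <- stats::runif(length(a1)) < p_miss
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }

  loci <- data.frame(
    locus_id = c(sprintf("msat_%02d", seq_len(Lm)), sprintf("snp_%04d", seq_len(Ls))),
    marker_class = marker_class,
    chromosome = as.character(sample.int(config$n_chromosomes, L, replace = TRUE)),
    stringsAsFactors = FALSE)
  data <- genotype_dataset(a1, a2, ids, pops, loci, alleles)
  names(true_freqs) <- loci$locus_id
  if (!is.null(pa1)) dimnames(pa1) <- dimnames(pa2) <- list(par_ids, loci$locus_id)
  truth <- structure(list(
    pedigree = data.frame(id = ids, pop = pops, sire = sire, dam = dam,
                          stringsAsFactors = FALSE),
    parent_genotypes = list(ids = par_ids, pop = par_pop, a1 = pa1, a2 = pa2),
    true_pop_freqs = true_freqs,
    true_F = stats::setNames(config$divergence_F, pop_names),
    bn_drift = stats::setNames(bn_drift, pop_names),
    config = config), class = "pedigree_truth")
  list(data = data, truth = truth)
}

#' @export
print.pedigree_truth <- function(x, ...) {
  noff <- sum(!is.na(x$pedigree$sire))
  cat(sprintf("pedigree_truth: %d sampled individuals (%d family offspring), %d unsampled parents\n",
              nrow(x$pedigree), noff, length(x$parent_genotypes$ids)))
  cat("true F:", paste(sprintf("%s=%.3g", names(x$true_F), x$true_F), collapse = ", "), "\n")
  invisible(x)
}

#' True relationship class of pairs of sampled individuals
#'
#' Classes are derived from the recorded pedigree: pairs sharing both parents
#' are full sibs, pairs sharing exactly one parent are half sibs, all other
#' sampled pairs are unrelated (family parents are unsampled founders, so
#' parent--offspring pairs do not occur among sampled individuals). Labels are
#' symmetric in the pair.
#'
#' @param truth a `pedigree_truth` object.
#' @param id1,id2 vectors of sampled individual ids (recycled).
#' @return character vector of relationship classes.
#' @export
pair_relationship <- function(truth, id1, id2) {
  ped <- truth$pedigree
  i <- match(id1, ped$id); j <- match(id2, ped$id)
  if (anyNA(i) || anyNA(j)) stop("unknown individual id")
  shared <- (!is.na(ped$sire[i]) & !is.na(ped$sire[j]) & ped$sire[i] == ped$sire[j]) +
            (!is.na(ped$dam[i]) & !is.na(ped$dam[j]) & ped$dam[i] == ped$dam[j])
  out <- c("unrelated", "halfsib", "fullsib")[shared + 1L]
  out[id1 == id2] <- NA_character_
  out
}

#' All within-population pairs with their true relationship class
#' @param truth a `pedigree_truth` object.
#' @param population population label.
#' @return data frame with columns `id1`, `id2`, `relationship`.
#' @export
relationship_pairs <- function(truth, population) {
  ids <- truth$pedigree$id[truth$pedigree$pop == population]
  if (length(ids) < 2) stop("need >= 2 individuals in population")
  pr <- utils::combn(ids, 2)
  data.frame(id1 = pr[1, ], id2 = pr[2, ],
             relationship = pair_relationship(truth, pr[1, ], pr[2, ]),
             stringsAsFactors = FALSE)
}

#' Wright--Fisher forward simulation of unlinked biallelic loci
#'
#' A discrete-generation, constant-size, random-mating diploid population
#' (two distinct parents per offspring) with free recombination between loci.
#' Genetic drift in the final generations generates the mixture linkage
#' disequilibrium that the LD method for effective population size estimates.
#' Loci fixed during the simulation are returned monomorphic (a downstream MAF
#' screen removes them).
#'
#' @param true_Ne population size (>= 2).
#' @param n_generations generations to evolve (>= 20 recommended so LD reaches
#'   its drift equilibrium).
#' @param n_loci number of unlinked biallelic loci; initial allele frequencies
#'   are drawn from U(0.1, 0.9).
#' @param sample_size individuals sampled (without replacement) from the final
#'   generation; must not exceed `true_Ne`.
#' @param seed integer seed.
#' @return a `geno_data` of SNP loci from one population `"wf"`.
#' @export
simulate_wright_fisher <- function(true_Ne, n_generations = 30, n_loci,
                                   sample_size, seed = 1) {
  if (true_Ne < 2) stop("true_Ne must be >= 2")
  if (sample_size > true_Ne) stop("cannot sample more individuals than the population holds")
  if (n_generations < 1) stop("n_generations must be >= 1")
  set.seed(seed)
  N <- as.integer(true_Ne); L <- as.integer(n_loci)
  p0 <- stats::runif(L, 0.1, 0.9)
  G <- matrix(stats::rbinom(N * L, 2, rep(p0, each = N)), N, L)
  gamete <- function(rows) {
    g <- G[rows, , drop = FALSE]
    (g == 2L) + (g == 1L) * (stats::runif(length(g)) < 0.5)
  }
  for (gen in seq_len(n_generations)) {
    s <- sample.int(N, N, replace = TRUE)
    d <- sample.int(N, N, replace = TRUE)
    clash <- which(d == s)
    while (length(clash)) {                       # two distinct parents
      d[clash] <- sample.int(N, length(clash), replace = TRUE)
      clash <- clash[d[clash] == s[clash]]
    }
    G <- gamete(s) + gamete(d)
    storage.mode(G) <- "integer"
  }
  take <- sample.int(N, sample_size)
  g <- G[take, , drop = FALSE]
  a1 <- ifelse(g >= 1L, 1L, 2L)                   # copies of allele 1
  a2 <- ifelse(g == 2L, 1L, 2L)
  loci <- data.frame(locus_id = sprintf("snp_%04d", seq_len(L)),
                     marker_class = "SNP", stringsAsFactors = FALSE)
  genotype_dataset(a1, a2, sprintf("wf_%03d", seq_len(sample_size)),
                   rep("wf", sample_size), loci,
                   rep(list(c("A", "C")), L))
}

#' Simulate genotype pairs of a known relationship class
#'
#' Draws, for each pair and locus, the number of alleles shared identical by
#' descent from the class's (k0, k1, k2) coefficients, then fills in allele
#' copies from the supplied population frequencies. Useful for calibrating the
#' pairwise sibship classifier.
#'
#' @param n_pairs number of pairs.
#' @param relationship one of `"unrelated"`, `"halfsib"`, `"fullsib"`,
#'   `"parentoffspring"`.
#' @param freqs list of per-locus allele frequency vectors, or a plain numeric
#'   vector of biallelic first-allele frequencies.
#' @param error_rate per-allele genotyping error applied after drawing.
#' @param seed integer seed.
#' @return list with `data` (a `geno_data`, individuals `pairK_a`/`pairK_b` in
#'   one population) and `pairs` (data frame `id1`, `id2`).
#' @export
simulate_relationship_pairs <- function(n_pairs, relationship, freqs,
                                        error_rate = 0, seed = 1) {
  kcoef <- ibd_coefficients()[[match.arg(relationship,
                                         names(ibd_coefficients()))]]
  if (is.numeric(freqs)) freqs <- lapply(freqs, function(p) c(p, 1 - p))
  set.seed(seed)
  L <- length(freqs); n <- as.integer(n_pairs)
  a1 <- matrix(NA_integer_, 2L * n, L); a2 <- a1
  odd <- seq(1L, 2L * n, by = 2L); evn <- odd + 1L
  for (l in seq_len(L)) {
    p <- freqs[[l]]; k <- length(p)
    m <- sample.int(3L, n, replace = TRUE, prob = kcoef) - 1L
    x1 <- sample.int(k, n, TRUE, p); x2 <- sample.int(k, n, TRUE, p)
    y1 <- sample.int(k, n, TRUE, p); y2 <- sample.int(k, n, TRUE, p)
    s <- sample.int(k, n, TRUE, p)
    g1a <- ifelse(m >= 1L, s, x1); g1b <- x2
    g2a <- ifelse(m >= 1L, s, y1); g2b <- ifelse(m == 2L, x2, y2)
    a1[odd, l] <- g1a; a2[odd, l] <- g1b
    a1[evn, l] <- g2a; a2[evn, l] <- g2b
  }
  n_alleles <- vapply(freqs, length, integer(1))
  e <- apply_genotype_error(a1, a2, n_alleles, error_rate)
  ids <- as.vector(rbind(sprintf("pair%04d_a", seq_len(n)),
                         sprintf("pair%04d_b", seq_len(n))))
  k <- n_alleles
  alleles <- lapply(k, function(ki) as.character(seq_len(ki)))
  loci <- data.frame(locus_id = sprintf("L%04d", seq_len(L)),
                     marker_class = ifelse(k == 2, "SNP", "microsatellite"),
                     stringsAsFactors = FALSE)
  data <- genotype_dataset(e$a1, e$a2, ids, rep("sim", 2L * n), loci, alleles)
  list(data = data,
       pairs = data.frame(id1 = ids[odd], id2 = ids[evn],
                          stringsAsFactors = FALSE))
}
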