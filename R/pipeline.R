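#' Derive a reproducible stage seed from the master seed
#'
#' Stage seeds are a deterministic function of the master seed and the stage
#' name, so any stage can be rerun standalone and reproduce its in-pipeline
#' output.
#'
#' @param master master seed (integer).
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 101) %% 2147483647)
}

read_pipeline_config <- function(config_path) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  defaults <- list(seed = 1, snp_individual_fraction = 0.625,
                   fst_permutations = 999, apply_filters = TRUE,
                   hwe_method = "chi2", hwe_n_permutations = 1000,
                   relatedness_sizes_msat = c(1, 2, 4, 8, 16),
                   relatedness_sizes_snp = c(1, 5, 10, 25, 50, 100),
                   relatedness_replicates = 200,
                   hhc_size_msat = 8, hhc_sizes_snp = c(100, 500, 1000),
                   hhc_replicates = 200, fullsib_prob = 0.95,
                   maf_cutoff = 0.02, confidence = 0.95)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("genepop_path", "vcf_path", "pop_map_path"))
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop("config references a missing input file: ", cfg[[nm]])
  cfg
}

sim_config_from_pipeline <- function(cfg) {
  args <- cfg[intersect(names(cfg), names(formals(sim_config)))]
  args$seed <- stage_seed(cfg$seed, "simulate")
  if (!is.null(args$n_individuals_per_pop))
    args$n_individuals_per_pop <- unlist(args$n_individuals_per_pop)
  if (!is.null(args$divergence_F)) args$divergence_F <- unlist(args$divergence_F)
  if (!is.null(cfg$family_plan))
    args$family_plan <- do.call(rbind, lapply(cfg$family_plan, as.data.frame))
  do.call(sim_config, args)
}

#' Run the full marker-comparison pipeline
#'
#' Orchestrates simulate -> filter -> the three-dataset analysis (full
#' microsatellite panel A; SNPs on a subset of "sequenced" individuals B;
#' microsatellites on those same individuals C) -> diversity, F_ST, Ne,
#' sibship, relatedness-precision and sMLH/HHC reports, plus a run manifest
#' with stage seeds, timings and output checksums. All outputs are
#' deterministic given the config (rerunning yields identical files); on a
#' stage error a `FAILED` marker file naming the stage is left in the output
#' directory.
#'
#' @param config_path plain-text (YAML key-value) configuration file. Any
#'   [sim_config()] field may be set; see the package vignette for the
#'   analysis keys. Alternatively `genepop_path`/`vcf_path`/`pop_map_path`
#'   load existing data instead of simulating.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config_path, out_dir) {
  cfg <- read_pipeline_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  current_stage <- "setup"
  res <- list(config = cfg)
  on.exit({
    if (!identical(current_stage, "done"))
      writeLines(paste("failed at stage:", current_stage),
                 file.path(out_dir, "FAILED"))
  })
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
    t0 <<- Sys.time()
    current_stage <<- stage
    message("[markercmp] stage: ", stage)
  }

  tick("simulate")
  truth <- NULL
  if (!is.null(cfg$genepop_path) || !is.null(cfg$vcf_path)) {
    parts <- list()
    if (!is.null(cfg$genepop_path)) parts$msat <- read_genepop(cfg$genepop_path)
    if (!is.null(cfg$vcf_path)) parts$snp <- read_vcf(cfg$vcf_path, cfg$pop_map_path)
    data <- if (length(parts) == 2) bind_loci(parts$msat, parts$snp) else parts[[1]]
  } else {
    sc <- sim_config_from_pipeline(cfg)
    sim <- simulate_dataset(sc)
    data <- sim$data; truth <- sim$truth
    write_genepop(subset_markers(data, "microsatellite"),
                  file.path(out_dir, "simulated_msat.gen"))
    write_vcf(subset_markers(data, "SNP"), file.path(out_dir, "simulated_snp.vcf"))
    write_pop_map(data, file.path(out_dir, "pop_map.tsv"))
    utils::write.table(truth$pedigree, file.path(out_dir, "pedigree.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res$truth <- truth

  # the three datasets: A = msat on everyone, B = SNP / C = msat on the
  # subset of individuals carried through to sequencing
  tick("datasets")
  set.seed(stage_seed(cfg$seed, "subset"))
  sub_ids <- unlist(lapply(unique(data$pops), function(p) {
    ids <- data$ids[data$pops == p]
    sample(ids, max(2, round(length(ids) * cfg$snp_individual_fraction)))
  }))
  sub_ids <- data$ids[data$ids %in% sub_ids]          # keep dataset order
  A <- subset_markers(data, "microsatellite")
  B <- subset_markers(data[sub_ids, ], "SNP")
  C <- subset_markers(data[sub_ids, ], "microsatellite")

  tick("filter")
  if (isTRUE(cfg$apply_filters)) {
    fc <- filter_config(hwe_method = cfg$hwe_method,
                        hwe_n_permutations = cfg$hwe_n_permutations,
                        hwe_seed = stage_seed(cfg$seed, "hwe"))
    fl <- apply_filter_chain(B, fc)
    B <- fl$data
    write_filter_report(fl$report, file.path(out_dir, "filter_report.tsv"))
    res$filter_report <- fl$report
    sub_ids <- B$ids
    C <- C[sub_ids, ]
  }

  tick("diversity")
  res$diversity <- lapply(list(A = A, B = B, C = C), diversity_table)
  for (nm in names(res$diversity))
    write_diversity_table(res$diversity[[nm]],
                          file.path(out_dir, paste0("diversity_", nm, ".tsv")))

  tick("ne")
  res$ne <- lapply(list(A = A, B = B, C = C), function(d) {
    lapply(stats::setNames(nm = unique(d$pops)), function(p)
      tryCatch(ld_ne(d, p, maf_cutoff = cfg$maf_cutoff,
                     confidence = cfg$confidence),
               error = function(e) NULL))
  })
  ne_rows <- do.call(rbind, lapply(names(res$ne), function(nm) {
    do.call(rbind, lapply(names(res$ne[[nm]]), function(p) {
      e <- res$ne[[nm]][[p]]
      if (is.null(e)) return(NULL)
      data.frame(dataset = nm, population = p, ne_raw = e$ne_raw,
                 ne_corrected = e$ne_corrected, ci_low = e$ci_low,
                 ci_high = e$ci_high)
    }))
  }))
  utils::write.table(ne_rows, file.path(out_dir, "ne_estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tick("fst")
  res$fst <- lapply(list(A = A, B = B, C = C), fst_matrix,
                    n_permutations = cfg$fst_permutations,
                    seed = stage_seed(cfg$seed, "fst"))
  for (nm in names(res$fst))
    write_fst_matrix(res$fst[[nm]], file.path(out_dir, paste0("fst_", nm, ".tsv")))

  tick("sibship")
  classes <- c("unrelated", "halfsib", "fullsib")
  # simulated error is per allele copy; the classifier's error model is per
  # genotype, so hand it the matching genotype-scale rates
  err <- c(SNP = if (is.null(cfg$error_rate_snp)) 0.05 else cfg$error_rate_snp,
           microsatellite = if (is.null(cfg$error_rate_msat)) 1e-4
                            else cfg$error_rate_msat)
  model <- relationship_model(error_rate = allele_to_genotype_error(err))
  res$sibship <- lapply(list(B = B, C = C), function(d) {
    lapply(stats::setNames(nm = unique(d$pops)), function(p)
      suppressWarnings(classify_pairs(d, p, model = model, classes = classes,
                                      fullsib_prob = cfg$fullsib_prob)))
  })
  sib_tab <- do.call(rbind, lapply(names(res$sibship), function(nm)
    cbind(dataset = nm, do.call(rbind, lapply(res$sibship[[nm]],
                                              `[[`, "family_table")))))
  utils::write.table(sib_tab, file.path(out_dir, "sibship_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tick("relatedness")
  res$precision <- list(
    B = subset_precision(B, pmin(cfg$relatedness_sizes_snp, n_loci(B)),
                         n_replicates = cfg$relatedness_replicates,
                         seed = stage_seed(cfg$seed, "precision_snp")),
    C = subset_precision(C, pmin(cfg$relatedness_sizes_msat, n_loci(C)),
                         n_replicates = cfg$relatedness_replicates,
                         seed = stage_seed(cfg$seed, "precision_msat")))
  write_relatedness(res$precision$B, file.path(out_dir, "precision_snp.tsv"))
  write_relatedness(res$precision$C, file.path(out_dir, "precision_msat.tsv"))

  tick("mlh")
  res$smlh <- list(B = smlh(B), C = smlh(C))
  res$cross_marker <- cross_marker_correlation(res$smlh$B, res$smlh$C)
  sizes_snp <- cfg$hhc_sizes_snp[2 * cfg$hhc_sizes_snp <= n_loci(B)]
  if (!length(sizes_snp)) sizes_snp <- floor(n_loci(B) / 2)
  res$hhc <- list(
    B = lapply(sizes_snp, function(s)
      hhc(B, s, n_replicates = cfg$hhc_replicates,
          seed = stage_seed(cfg$seed, paste0("hhc_snp", s)))),
    C = list(hhc(C, min(cfg$hhc_size_msat, floor(n_loci(C) / 2)),
                 n_replicates = cfg$hhc_replicates,
                 seed = stage_seed(cfg$seed, "hhc_msat"))))
  hhc_tab <- do.call(rbind, lapply(names(res$hhc), function(nm)
    do.call(rbind, lapply(res$hhc[[nm]], function(h)
      data.frame(dataset = nm, subset_size = h$subset_size,
                 mean_r = mean(h$r, na.rm = TRUE),
                 n_degenerate = h$n_degenerate)))))
  utils::write.table(hhc_tab, file.path(out_dir, "hhc_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = names(res$smlh$B), smlh_snp = unname(res$smlh$B),
               smlh_msat = unname(res$smlh$C[names(res$smlh$B)])),
    file.path(out_dir, "smlh.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  tick("report")
  res$comparison <- compare_markers_report(res)
  utils::write.table(res$comparison$summary,
                     file.path(out_dir, "comparison_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tick("manifest")
  outputs <- setdiff(list.files(out_dir), c("manifest.yaml", "FAILED"))
  manifest <- list(
    config = cfg,
    stage_seeds = lapply(stats::setNames(nm = c("simulate", "subset", "hwe",
                                                "fst", "precision_snp",
                                                "precision_msat", "hhc_msat")),
                         function(s) stage_seed(cfg$seed, s)),
    package_version = as.character(utils::packageVersion("markercmp")),
    r_version = as.character(getRversion()),
    checksums = as.list(tools::md5sum(file.path(out_dir, outputs))),
    timings_sec = timings)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  current_stage <- "done"
  invisible(res)
}

# largest grid point whose error is not zero by construction (the full panel
# reproduces itself exactly, so the top grid point is skipped when it equals
# the panel size)
precision_near_top <- function(pc) {
  v <- pc$summary$mean[pc$summary$mean > 0]
  if (!length(v)) return(0)
  utils::tail(v, 1)
}

# concatenate the loci of two datasets over the same individuals
bind_loci <- function(x, y) {
  if (!identical(sort(x$ids), sort(y$ids)))
    stop("datasets cover different individuals")
  y <- y[x$ids, ]
  genotype_dataset(cbind(x$a1, y$a1), cbind(x$a2, y$a2), x$ids, x$pops,
                   rbind(x$loci, y$loci), c(x$alleles, y$alleles))
}

#' Side-by-side marker-class comparison summary
#'
#' Collates the stage results of [run_pipeline()] into one table comparing
#' the SNP and microsatellite analyses on the same individuals: global and
#' pairwise F_ST agreement, sibship classification (against the simulated
#' pedigree truth when available), relatedness subset precision at the top of
#' each marker's subset grid, and mean HHC. Every number is taken from the
#' stage outputs -- nothing is recomputed.
#'
#' @param res result list of [run_pipeline()] (needs elements `fst`,
#'   `sibship`, `precision`, `hhc`, `smlh`; `truth` optional).
#' @return list with `summary` (long data frame: metric, snp, msat) and
#'   `fst_delta` (pairwise F_ST differences SNP - msat).
#' @export
compare_markers_report <- function(res) {
  if (!identical(names(res$smlh$B), names(res$smlh$C)))
    stop("marker datasets cover different individuals: ",
         paste(c(setdiff(names(res$smlh$B), names(res$smlh$C)),
                 setdiff(names(res$smlh$C), names(res$smlh$B))), collapse = ", "))
  fst_b <- res$fst$B; fst_c <- res$fst$C
  delta <- fst_b$pairwise - fst_c$pairwise[rownames(fst_b$pairwise),
                                           colnames(fst_b$pairwise)]
  rows <- list(
    data.frame(metric = "global_fst", snp = fst_b$global_fst,
               msat = fst_c$global_fst),
    data.frame(metric = "mean_abs_pairwise_fst_delta",
               snp = mean(abs(delta[lower.tri(delta)])), msat = 0))
  sib_acc <- function(nm) {
    if (is.null(res$truth)) return(NULL)
    hits <- 0L; tot <- 0L
    for (p in names(res$sibship[[nm]])) {
      prs <- res$sibship[[nm]][[p]]$pairs
      tr <- pair_relationship(res$truth, prs$id1, prs$id2)
      rel <- tr %in% c("fullsib", "halfsib")
      hits <- hits + sum(prs$class[rel] == tr[rel])
      tot <- tot + sum(rel)
    }
    if (tot == 0) NA_real_ else hits / tot
  }
  acc <- c(snp = sib_acc("B"), msat = sib_acc("C"))
  if (!is.null(res$truth))
    rows <- c(rows, list(data.frame(metric = "sibship_accuracy_related_pairs",
                                    snp = acc["snp"], msat = acc["msat"])))
  mp <- vapply(c("B", "C"), function(nm)
    mean(unlist(lapply(res$sibship[[nm]], function(s) s$pairs$probability)),
         na.rm = TRUE), numeric(1))
  rows <- c(rows, list(
    data.frame(metric = "sibship_mean_class_probability",
               snp = mp[["B"]], msat = mp[["C"]]),
    data.frame(metric = "precision_error_curve_mean",
               snp = mean(res$precision$B$summary$mean),
               msat = mean(res$precision$C$summary$mean)),
    data.frame(metric = "precision_error_near_top",
               snp = utils::tail(res$precision$B$summary$mean, 1),
               msat = precision_near_top(res$precision$C)),
    data.frame(metric = "mean_hhc",
               snp = mean(vapply(res$hhc$B, function(h)
                 mean(h$r, na.rm = TRUE), numeric(1))),
               msat = mean(vapply(res$hhc$C, function(h)
                 mean(h$r, na.rm = TRUE), numeric(1)))),
    data.frame(metric = "cross_marker_smlh_r", snp = res$cross_marker$r,
               msat = res$cross_marker$r)))
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, fst_delta = delta)
}
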