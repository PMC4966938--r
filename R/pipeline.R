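#' Pipeline configuration
#'
#' Collects file paths and every analysis constant, all defaulting to the
#' published settings: segmentation gamma = 100 / kmin = 5, aberration
#' cutoff 0.1, variance filter 0.03, difference cutoff 0.1, complexity
#' prognostic threshold 25%, blacklist frequency 0.10, 36-month horizon.
#'
#' @param lrr path to the probe-level LRR table.
#' @param clinical path to the clinical CSV (required when survival
#'   analyses are requested).
#' @param out output directory.
#' @param blacklist optional blacklist TSV (`chrom`, `start`, `end`).
#' @param genome_scale genome scaling factor.
#' @param gamma,kmin segmentation parameters.
#' @param variance_cutoff,aberration_cutoff,diff_cutoff,complexity_threshold,
#'   blacklist_freq,horizon analysis constants.
#' @param n_boot bootstrap replicates for cluster support (0 disables).
#' @param seed seed for the bootstrap.
#' @param survival run the survival analyses (default TRUE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(lrr, clinical = NULL, out = "methet_out",
                            blacklist = NULL, genome_scale = 1,
                            gamma = 100, kmin = 5,
                            variance_cutoff = 0.03, aberration_cutoff = 0.1,
                            diff_cutoff = 0.1, complexity_threshold = 25,
                            blacklist_freq = 0.10, horizon = 36,
                            n_boot = 0, seed = 1, survival = TRUE) {
  cfg <- list(lrr = lrr, clinical = clinical, out = out,
              blacklist = blacklist, genome_scale = genome_scale,
              gamma = gamma, kmin = kmin,
              variance_cutoff = variance_cutoff,
              aberration_cutoff = aberration_cutoff,
              diff_cutoff = diff_cutoff,
              complexity_threshold = complexity_threshold,
              blacklist_freq = blacklist_freq, horizon = horizon,
              n_boot = n_boot, seed = seed, survival = survival)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified keys keep the [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' filter -> segment -> atomic segments -> heterogeneity + complexity ->
#' clustering (optional) -> survival, from one configuration, with one log
#' line per stage. All result tables are written under the configured
#' output directory and returned.
#'
#' @param cfg a `pipeline_config` (or a YAML path).
#' @return result bundle: list with `segments`, `atoms`, `heterogeneity`,
#'   `complexity`, `strata`, `km`, `cox`, `cluster_purity`, `log`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log <<- c(log, line)
  }
  # ---- validation before compute
  if (!file.exists(cfg$lrr)) stop("stage config: LRR file not found: ", cfg$lrr)
  if (cfg$survival && (is.null(cfg$clinical) || !file.exists(cfg$clinical)))
    stop("stage config: survival requested but clinical file missing")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  genome <- genome_hg19(cfg$genome_scale)
  lrr <- stage("read_lrr", read_lrr_table(cfg$lrr, genome))
  say("read_lrr: %d probes x %d samples", nrow(lrr$probes),
      length(lrr$samples))
  clinical <- NULL
  if (!is.null(cfg$clinical)) {
    clinical <- stage("read_clinical", read_clinical(cfg$clinical))
    say("read_clinical: %d samples, %d patients", nrow(clinical),
        length(unique(clinical$patient)))
  }
  blk <- NULL
  if (!is.null(cfg$blacklist)) {
    blk <- utils::read.delim(cfg$blacklist, stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character"))
    say("blacklist: %d regions, %d bp", nrow(blk),
        sum(blk$end - blk$start + 1))
  }
  lrr <- stage("filter", suppressMessages(apply_filters(lrr, blk)))
  say("filter: %d probes retained", nrow(lrr$probes))

  params <- seg_params(gamma = cfg$gamma, kmin = cfg$kmin)
  segments <- stage("segment", suppressMessages(
    segment_profiles(lrr, params)))
  say("segment: %d segments over %d samples (gamma=%g, kmin=%d)",
      nrow(segments), length(unique(segments$sample)), cfg$gamma, cfg$kmin)

  first <- if (is.null(clinical)) lrr$samples else
    clinical$sample[clinical$resection == 1]
  seg1 <- segments[segments$sample %in% first, , drop = FALSE]
  atoms <- stage("atoms", atomic_segments(seg1, lrr$probes))
  say("atoms: %d atomic segments x %d first-resection samples",
      nrow(atoms$atoms), length(atoms$samples))

  if (is.null(clinical)) {
    # without sample-patient mapping, only per-sample complexity is possible
    cx <- data.frame(sample = unique(segments$sample))
    cx$percent <- vapply(cx$sample, function(s) genomic_complexity(
      segments[segments$sample == s, ], cfg$aberration_cutoff), numeric(1))
    out <- list(segments = segments, atoms = atoms,
                complexity = list(samples = cx), log = log)
    write_bundle(out, cfg)
    return(invisible(out))
  }

  het_e <- stage("heterogeneity", cohort_heterogeneity(
    atoms, clinical, "euclidean", variance_cutoff = cfg$variance_cutoff))
  het_p <- stage("heterogeneity", cohort_heterogeneity(
    atoms, clinical, "proportion_genome", diff_cutoff = cfg$diff_cutoff))
  say("heterogeneity: %d of %d patients scored (euclidean median %.2f)",
      sum(!is.na(het_e$score)), nrow(het_e),
      stats::median(het_e$score, na.rm = TRUE))
  cx <- stage("complexity", cohort_complexity(segments, clinical,
                                              cfg$aberration_cutoff))
  say("complexity: patient-wise median %.1f%%",
      stats::median(cx$patients$percent, na.rm = TRUE))

  purity_tab <- NULL
  if (cfg$n_boot > 0) {
    tree <- stage("cluster", multiscale_bootstrap(
      atoms, cfg$variance_cutoff, n_boot = cfg$n_boot, seed = cfg$seed))
    purity_tab <- patient_cluster_purity(tree, clinical)
    say("cluster: %d monophyletic / %d split / %d not assessable",
        sum(purity_tab$status == "monophyletic"),
        sum(purity_tab$status == "split"),
        sum(purity_tab$status == "not assessable"))
  } else tree <- NULL

  # ---- survival analyses on multi-deposit patients
  pat <- cohort_patients(clinical)
  idx <- match(pat$patient, het_e$patient)
  pat$het <- het_e$score[idx]
  pat$het_prop <- het_p$score[match(pat$patient, het_p$patient)]
  pat$cx <- cx$patients$percent[match(pat$patient, cx$patients$patient)]
  multi <- pat[!is.na(pat$het), , drop = FALSE]
  multi$het_group <- median_split(multi$het)
  multi$strata3 <- combined_strata(multi$het, multi$cx,
                                   cfg$complexity_threshold)
  say("strata: %d low / %d high heterogeneity; combined %s",
      sum(multi$het_group == "low"), sum(multi$het_group == "high"),
      paste(table(multi$strata3), collapse = "/"))

  km <- list(); cox <- list(); trend <- list()
  for (ep in c("pfs", "os")) {
    tm <- multi[[paste0(ep, "_time")]]
    ev <- multi[[paste0(ep, "_event")]]
    km[[ep]] <- three_year_rate(tm, ev, multi$het_group, cfg$horizon)
    covars <- data.frame(
      het_low = as.integer(multi$het_group == "low"),
      cx_low = as.integer(multi$cx < cfg$complexity_threshold),
      age = multi$age,
      sex_female = as.integer(multi$sex == "F"),
      synchronous = multi$synchronous,
      chemo = multi$chemo)
    cox[[ep]] <- stage("cox", cox_screen(tm, ev, covars,
                                         horizon = cfg$horizon))
    st3 <- droplevels(multi$strata3)
    trend[[ep]] <- if (nlevels(st3) >= 2L)
      logrank_trend(tm, ev, st3, cfg$horizon)
    else list(chisq = NA_real_, df = 1L, p = NA_real_, table = NULL)
    say("%s: 3-yr rate low %.0f%% / high %.0f%%; trend p = %.3g",
        toupper(ep), km[[ep]]$rate[km[[ep]]$group == "low"],
        km[[ep]]$rate[km[[ep]]$group == "high"], trend[[ep]]$p)
  }

  out <- list(segments = segments, atoms = atoms,
              heterogeneity = list(euclidean = het_e, proportion = het_p),
              complexity = cx, patients = multi, km = km, cox = cox,
              trend = trend, tree = tree, cluster_purity = purity_tab,
              log = log)
  write_bundle(out, cfg)
  invisible(out)
}

write_bundle <- function(out, cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  write_segments(out$segments, file.path(cfg$out, "segments.tsv"))
  if (!is.null(out$heterogeneity)) {
    he <- out$heterogeneity$euclidean
    he$proportion <- out$heterogeneity$proportion$score[
      match(he$patient, out$heterogeneity$proportion$patient)]
    utils::write.table(he, file.path(cfg$out, "heterogeneity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(out$complexity$patients))
    utils::write.table(out$complexity$patients,
                       file.path(cfg$out, "complexity.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(out$patients))
    utils::write.table(out$patients, file.path(cfg$out, "patients.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(out$km)) {
    km <- do.call(rbind, lapply(names(out$km), function(ep)
      cbind(endpoint = ep, out$km[[ep]])))
    utils::write.table(km, file.path(cfg$out, "km_rates.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    cox <- do.call(rbind, lapply(names(out$cox), function(ep)
      cbind(endpoint = ep, out$cox[[ep]]$univariable)))
    utils::write.table(cox, file.path(cfg$out, "cox_univariable.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeLines(out$log, file.path(cfg$out, "pipeline.log"))
  invisible(NULL)
}
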