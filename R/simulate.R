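#' Configuration for the synthetic multi-deposit metastasis cohort
#'
#' The generator emulates the structure the analysis assumes: each patient
#' carries a clonal ancestor copy-number profile (diploid plus a Poisson
#' number of arm-level or focal events, with event placement weighted
#' towards the arms recurrently gained — 7p, 7q, 8q, 13q, 20q — and lost —
#' 1p, 4p, 4q, 8p, 17p, 18q — in colorectal liver metastases), and every
#' metastatic deposit adds its own Poisson number of branch-private
#' events. Rendered probe data dilute the tumour signal by sample purity
#' and add Gaussian probe noise; survival times follow an exponential
#' hazard that depends on the patient's true heterogeneity.
#'
#' Default cohort conditions follow the study design this pipeline
#' addresses: 45 patients, 1-7 deposits per patient (mean ~2.7, median 2),
#' purity uniform on 0.26-0.95, a low copy-neutral LOH rate, 30%
#' censoring, and low-vs-high heterogeneity hazard ratios of 0.4
#' (progression) and 0.3 (death).
#'
#' @param n_patients number of patients.
#' @param deposit_probs probability of 1..7 first-resection deposits.
#' @param genome_scale genome scaling factor passed to [genome_hg19()];
#'   event lengths scale with it, so all fractions are preserved.
#' @param probe_spacing marker spacing in (scaled) bp.
#' @param lambda_anc mean ancestor (clonal) copy-number events.
#' @param lambda_div mean branch-private events per deposit. The rate is a
#'   patient-level trait: each patient draws a private-event rate from an
#'   exponential distribution with this mean, and every deposit adds
#'   `Poisson(rate)` private events. The mixing reproduces the wide
#'   between-patient spread of inter-metastatic heterogeneity seen in
#'   multi-deposit cohorts (some patients near-clonal, others with
#'   deposits as different as unrelated tumours).
#' @param lambda_cnloh mean ancestor copy-neutral LOH events.
#' @param p_arm probability an event is arm-level rather than focal.
#' @param focal_mean_bp,focal_min_bp focal event length distribution
#'   (shifted exponential), in unscaled bp.
#' @param arm_weight_boost placement weight multiplier for the recurrent
#'   arms in the matching direction.
#' @param purity_range cohort purity (cancer cell fraction) range. Purity
#'   is hierarchical: each patient draws a mean purity uniformly from the
#'   interior of this range and each deposit scatters around it (sd 0.1,
#'   clamped to the range), since deposits of one patient share etiology
#'   and tissue handling. This keeps the cohort-wide purity spread wide
#'   while the within-patient spread stays moderate.
#' @param ccf_fail_prob probability a sample's purity estimate is missing.
#' @param noise_sd Gaussian probe noise standard deviation (LRR units).
#' @param min_lrr floor for the log ratio of zero total copies.
#' @param n_second_patients patients also sampled at a second resection.
#' @param pfs_median_months,os_median_months baseline (low-heterogeneity
#'   group) exponential medians.
#' @param pfs_hr,os_hr hazard ratio low-vs-high heterogeneity (< 1: low
#'   heterogeneity is protective).
#' @param censoring target fraction of subjects censored before the event.
#' @param seed master seed (mandatory); every patient derives its own
#'   stream from it, so per-patient output is invariant to cohort size.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 45,
                       deposit_probs = c(0.10, 0.45, 0.22, 0.12, 0.06,
                                         0.03, 0.02),
                       genome_scale = 1,
                       probe_spacing = 700,
                       lambda_anc = 25,
                       lambda_div = 6,
                       lambda_cnloh = 2,
                       p_arm = 0.5,
                       focal_mean_bp = 1e7,
                       focal_min_bp = 1e6,
                       arm_weight_boost = 5,
                       purity_range = c(0.26, 0.95),
                       ccf_fail_prob = 0.045,
                       noise_sd = 0.15,
                       min_lrr = -4,
                       n_second_patients = 8,
                       pfs_median_months = 12,
                       os_median_months = 30,
                       pfs_hr = 0.4,
                       os_hr = 0.3,
                       censoring = 0.3,
                       seed) {
  if (missing(seed)) stop("a master seed is mandatory")
  stopifnot(n_patients >= 1, all(deposit_probs >= 0), sum(deposit_probs) > 0,
            genome_scale > 0, probe_spacing >= 1,
            lambda_anc >= 0, lambda_div >= 0, lambda_cnloh >= 0,
            p_arm >= 0, p_arm <= 1,
            purity_range[1] > 0, purity_range[2] <= 1,
            noise_sd >= 0, censoring >= 0, censoring <= 1,
            pfs_hr > 0, os_hr > 0)
  cfg <- list(n_patients = n_patients, deposit_probs = deposit_probs,
              genome = genome_hg19(genome_scale),
              genome_scale = genome_scale,
              probe_spacing = probe_spacing, lambda_anc = lambda_anc,
              lambda_div = lambda_div, lambda_cnloh = lambda_cnloh,
              p_arm = p_arm,
              focal_mean_bp = focal_mean_bp * genome_scale,
              focal_min_bp = focal_min_bp * genome_scale,
              arm_weight_boost = arm_weight_boost,
              purity_range = purity_range, ccf_fail_prob = ccf_fail_prob,
              noise_sd = noise_sd, min_lrr = min_lrr,
              n_second_patients = n_second_patients,
              pfs_median_months = pfs_median_months,
              os_median_months = os_median_months,
              pfs_hr = pfs_hr, os_hr = os_hr, censoring = censoring,
              seed = as.integer(seed))
  cfg$gain_arms <- c("7p", "7q", "8q", "13q", "20q")
  cfg$loss_arms <- c("1p", "4p", "4q", "8p", "17p", "18q")
  class(cfg) <- "sim_config"
  cfg
}

draw_purity <- function(cfg, purity_mean, n) {
  pmin(cfg$purity_range[2],
       pmax(cfg$purity_range[1], purity_mean + stats::rnorm(n, 0, 0.1)))
}

# deterministic derived seed: independent stream per (patient, purpose)
derive_seed <- function(master, i, stream = 0L) {
  as.integer((as.double(master %% 1000003L) * 1009 + i * 131071 +
                stream * 7919) %% 2147483629 + 1)
}

# --- integer copy-number profile manipulation -----------------------------

diploid_profile <- function(genome) {
  data.frame(chrom = genome$chrom, start = 1, end = genome$length,
             nA = 1L, nB = 1L, stringsAsFactors = FALSE)
}

# split the segments of one profile at [start, end] on chrom and apply
# delta to one allele (or a cnLOH transfer), clipping at zero
apply_event <- function(profile, chrom, start, end, allele, delta,
                        cnloh = FALSE) {
  rows <- profile[profile$chrom == chrom, , drop = FALSE]
  other <- profile[profile$chrom != chrom, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$end < start || r$start > end) { out[[length(out) + 1L]] <- r; next }
    if (r$start < start)
      out[[length(out) + 1L]] <- transform_seg(r, r$start, start - 1)
    ov <- transform_seg(r, max(r$start, start), min(r$end, end))
    if (cnloh) {
      if (ov$nA > 0L) { ov$nA <- ov$nA - 1L; ov$nB <- ov$nB + 1L }
    } else if (allele == 1L) {
      ov$nA <- max(0L, ov$nA + delta)
    } else {
      ov$nB <- max(0L, ov$nB + delta)
    }
    out[[length(out) + 1L]] <- ov
    if (r$end > end)
      out[[length(out) + 1L]] <- transform_seg(r, end + 1, r$end)
  }
  res <- rbind(other, do.call(rbind, out))
  res <- res[order(match(res$chrom, unique(profile$chrom)), res$start), ]
  rownames(res) <- NULL
  merge_equal_segments(res)
}

transform_seg <- function(r, s, e) { r$start <- s; r$end <- e; r }

merge_equal_segments <- function(profile) {
  if (nrow(profile) < 2L) return(profile)
  keep <- rep(TRUE, nrow(profile))
  for (i in 2:nrow(profile)) {
    same <- profile$chrom[i] == profile$chrom[i - 1] &&
      profile$nA[i] == profile$nA[i - 1] &&
      profile$nB[i] == profile$nB[i - 1]
    if (same) {
      profile$start[i] <- profile$start[i - 1]
      # propagate merged start backwards through the kept row
      profile$start[i] <- min(profile$start[i], profile$start[i - 1])
      keep[i - 1] <- FALSE
    }
  }
  out <- profile[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# draw one event's genomic span and direction
draw_event <- function(cfg, arms, cnloh = FALSE) {
  direction <- if (cnloh) 0L else sample(c(1L, -1L), 1)
  w <- arms$end - arms$start + 1
  if (!cnloh) {
    fav <- if (direction == 1L) cfg$gain_arms else cfg$loss_arms
    w <- w * ifelse(arms$name %in% fav, cfg$arm_weight_boost, 1)
  }
  a <- arms[sample.int(nrow(arms), 1, prob = w), ]
  if (stats::runif(1) < cfg$p_arm) {
    start <- a$start; end <- a$end
  } else {
    len <- cfg$focal_min_bp +
      stats::rexp(1, 1 / max(cfg$focal_mean_bp - cfg$focal_min_bp, 1))
    len <- max(1, round(len))
    start <- a$start + floor(stats::runif(1) * max(a$end - a$start, 1))
    end <- min(a$end, start + len - 1)
  }
  list(chrom = a$chrom, start = start, end = end,
       allele = sample(1:2, 1), delta = direction, cnloh = cnloh)
}

apply_random_events <- function(profile, cfg, arms, n_copy, n_cnloh = 0L) {
  for (k in seq_len(n_copy)) {
    ev <- draw_event(cfg, arms, cnloh = FALSE)
    profile <- apply_event(profile, ev$chrom, ev$start, ev$end,
                           ev$allele, ev$delta)
  }
  for (k in seq_len(n_cnloh)) {
    ev <- draw_event(cfg, arms, cnloh = TRUE)
    profile <- apply_event(profile, ev$chrom, ev$start, ev$end,
                           1L, 0L, cnloh = TRUE)
  }
  profile
}

# --- truth summaries ------------------------------------------------------

profile_ploidy <- function(profile) {
  len <- profile$end - profile$start + 1
  sum((profile$nA + profile$nB) * len) / sum(len)
}

profile_aberrant_fraction <- function(profile) {
  len <- profile$end - profile$start + 1
  sum(len[profile$nA + profile$nB != 2L]) / sum(len)
}

profile_cnloh_fraction <- function(profile) {
  len <- profile$end - profile$start + 1
  is_cnloh <- pmin(profile$nA, profile$nB) == 0L &
    pmax(profile$nA, profile$nB) == 2L
  sum(len[is_cnloh]) / sum(len)
}

#' True differing-genome fraction between two integer profiles
#'
#' Fraction of base pairs where the total copy numbers of two truth
#' profiles differ, computed on the union of their breakpoints.
#'
#' @param a,b truth profiles (data frames `chrom`, `start`, `end`, `nA`,
#'   `nB`).
#' @return fraction in [0, 1].
#' @export
true_differing_fraction <- function(a, b) {
  tot <- 0; diffbp <- 0
  for (chr in unique(a$chrom)) {
    ra <- a[a$chrom == chr, ]; rb <- b[b$chrom == chr, ]
    cuts <- sort(unique(c(ra$start, rb$start)))
    ends <- c(cuts[-1] - 1, max(ra$end))
    ia <- findInterval(cuts, ra$start); ib <- findInterval(cuts, rb$start)
    ta <- ra$nA[ia] + ra$nB[ia]; tb <- rb$nA[ib] + rb$nB[ib]
    len <- ends - cuts + 1
    tot <- tot + sum(len)
    diffbp <- diffbp + sum(len[ta != tb])
  }
  diffbp / tot
}

# --- patient- and cohort-level simulation ---------------------------------

#' Simulate one patient's truth profiles
#'
#' Draws the clonal ancestor (diploid plus `Poisson(lambda_anc)` copy
#' events and `Poisson(lambda_cnloh)` copy-neutral LOH events) and one
#' branch per deposit (`Poisson(lambda_div)` private events each), along
#' with purity per deposit and the truth summaries used by the recovery
#' tests.
#'
#' @param cfg a [sim_config()].
#' @param i patient index (drives the patient's private RNG stream).
#' @return list with `patient`, `deposits` (list of truth profiles),
#'   `purity`, `ploidy`, `true_divergence` (mean pairwise differing-bp
#'   fraction), `pairwise` (matrix), `aberrant_fraction` and
#'   `cnloh_fraction` per deposit, and clinical covariates.
#' @export
simulate_patient <- function(cfg, i) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, i, 0L))
  arms <- genome_arms(cfg$genome)
  n_dep <- sample.int(length(cfg$deposit_probs), 1, prob = cfg$deposit_probs)
  ancestor <- apply_random_events(diploid_profile(cfg$genome), cfg, arms,
                                  stats::rpois(1, cfg$lambda_anc),
                                  stats::rpois(1, cfg$lambda_cnloh))
  # patient-level divergence rate (exponential mixing around lambda_div)
  rate_div <- if (cfg$lambda_div > 0) stats::rexp(1, 1 / cfg$lambda_div)
  else 0
  deposits <- lapply(seq_len(n_dep), function(d)
    apply_random_events(ancestor, cfg, arms, stats::rpois(1, rate_div)))
  shrink <- min(0.1, diff(cfg$purity_range) / 2)
  purity_mean <- stats::runif(1, cfg$purity_range[1] + shrink,
                              cfg$purity_range[2] - 0.9 * shrink)
  purity <- draw_purity(cfg, purity_mean, n_dep)
  pw <- matrix(0, n_dep, n_dep)
  if (n_dep >= 2L)
    for (a in 1:(n_dep - 1)) for (b in (a + 1):n_dep)
      pw[a, b] <- pw[b, a] <- true_differing_fraction(deposits[[a]],
                                                      deposits[[b]])
  covar <- list(
    age = min(83, max(41, round(stats::rnorm(1, 63, 9)))),
    sex = sample(c("M", "F"), 1, prob = c(25, 20)),
    synchronous = stats::rbinom(1, 1, 20 / 45),
    chemo = stats::rbinom(1, 1, 25 / 41),
    tp53 = sample(c("wildtype", "mutated", "heterogeneous"), 1,
                  prob = c(0.38, 0.51, 0.11)))
  list(patient = sprintf("P%02d", i), deposits = deposits, purity = purity,
       purity_mean = purity_mean,
       ploidy = vapply(deposits, profile_ploidy, numeric(1)),
       true_divergence = if (n_dep >= 2L)
         mean(pw[upper.tri(pw)]) else NA_real_,
       pairwise = pw,
       aberrant_fraction = vapply(deposits, profile_aberrant_fraction,
                                  numeric(1)),
       cnloh_fraction = vapply(deposits, profile_cnloh_fraction, numeric(1)),
       ancestor = ancestor, covariates = covar)
}

#' Marker panel at fixed spacing over a genome
#'
#' @param genome a `genome_build`.
#' @param spacing inter-marker distance in bp.
#' @return probe data frame `marker`, `chrom`, `pos`, `class`.
#' @export
make_probes <- function(genome, spacing) {
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    first <- max(1, spacing %/% 2)
    if (first > genome$length[i]) return(NULL)
    pos <- seq.int(first, genome$length[i], by = spacing)
    data.frame(marker = sprintf("m%s_%06d", genome$chrom[i], seq_along(pos)),
               chrom = genome$chrom[i], pos = pos, class = "SNP",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stop("no probes: spacing too large")
  out
}

#' Render probe-level log R ratios from a truth profile
#'
#' Two-component mixture of tumour and admixed normal cells: the expected
#' intensity at a locus with tumour total copies n is
#' `((1 - rho) * 2 + rho * n) / 2` relative to the diploid reference, its
#' log2 giving the noiseless LRR; Gaussian probe noise is added on top.
#' Zero intensity (total copies 0 at purity 1) is floored at `min_lrr`.
#'
#' @param profile truth profile (`chrom`, `start`, `end`, `nA`, `nB`).
#' @param purity sample purity rho in (0, 1].
#' @param noise_sd Gaussian probe noise sd.
#' @param probes probe data frame (`chrom`, `pos`).
#' @param min_lrr floor value.
#' @return numeric LRR vector aligned with `probes`.
#' @export
render_lrr <- function(profile, purity, noise_sd, probes, min_lrr = -4) {
  stopifnot(purity > 0, purity <= 1)
  lrr <- numeric(nrow(probes))
  for (chr in unique(probes$chrom)) {
    ip <- which(probes$chrom == chr)
    seg <- profile[profile$chrom == chr, , drop = FALSE]
    j <- findInterval(probes$pos[ip], seg$start)
    total <- seg$nA[j] + seg$nB[j]
    intensity <- ((1 - purity) * 2 + purity * total) / 2
    lrr[ip] <- ifelse(intensity > 0, pmax(log2(pmax(intensity, 0)), min_lrr),
                      min_lrr)
  }
  if (noise_sd > 0) lrr <- lrr + stats::rnorm(length(lrr), 0, noise_sd)
  lrr
}

#' Simulate survival endpoints from true heterogeneity
#'
#' Exponential event times with hazard `h0 * exp(beta)` for patients whose
#' true heterogeneity lies above the cohort median (beta = -log(HR),
#' HR = low-vs-high hazard ratio < 1), independently censored by a
#' Uniform(0, u) time with u calibrated so the expected censored fraction
#' matches the configured value. A censoring fraction of 1 yields no
#' events at all.
#'
#' @param het_true per-patient true heterogeneity (drives the median split;
#'   `NA` assigned to the low-hazard group).
#' @param median_months baseline (low group) exponential median.
#' @param hr hazard ratio low-vs-high.
#' @param censoring target censored fraction.
#' @param seed RNG seed.
#' @return data frame `time` (months), `event`, `group`.
#' @export
simulate_survival <- function(het_true, median_months, hr, censoring, seed) {
  set.seed(seed)
  high <- !is.na(het_true) & het_true > stats::median(het_true, na.rm = TRUE)
  h0 <- log(2) / median_months
  rate <- h0 * ifelse(high, 1 / hr, 1)
  t_event <- stats::rexp(length(rate), rate)
  if (censoring >= 1) {
    return(data.frame(time = t_event, event = 0L,
                      group = ifelse(high, "high", "low")))
  }
  if (censoring <= 0) {
    return(data.frame(time = t_event, event = 1L,
                      group = ifelse(high, "high", "low")))
  }
  # E[P(C < T)] for C ~ U(0, u), T ~ Exp(rate): mean over subjects
  cens_frac <- function(u)
    mean((1 - exp(-rate * u)) / (rate * u)) - censoring
  u <- stats::uniroot(cens_frac, c(1e-6, 1e6))$root
  c_time <- stats::runif(length(rate), 0, u)
  data.frame(time = pmin(t_event, c_time),
             event = as.integer(t_event <= c_time),
             group = ifelse(high, "high", "low"))
}

#' Simulate a full cohort
#'
#' Generates every patient's truth profiles, renders the probe-level LRR
#' matrix, assembles the clinical table (including survival endpoints
#' coupled to true heterogeneity) and the allele-specific truth profiles.
#'
#' @param cfg a [sim_config()].
#' @return list with `lrr` (an `lrr_matrix`), `truth` (an
#'   `allele_profiles` with per-sample purity/ploidy), `clinical` (a
#'   `cohort_table`), `patients` (per-patient truth list) and `probes`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probes <- make_probes(cfg$genome, cfg$probe_spacing)
  pats <- lapply(seq_len(cfg$n_patients), function(i) simulate_patient(cfg, i))
  second_ids <- if (cfg$n_second_patients > 0) {
    set.seed(derive_seed(cfg$seed, 0L, 5L))
    sample(seq_len(cfg$n_patients), min(cfg$n_second_patients,
                                        cfg$n_patients))
  } else integer(0)

  vals <- list(); seg_rows <- list(); meta_rows <- list(); clin_rows <- list()
  for (i in seq_along(pats)) {
    p <- pats[[i]]
    n_dep <- length(p$deposits)
    arms <- genome_arms(cfg$genome)
    # optional second-resection deposits, drawn from the same ancestor
    n_second <- if (i %in% second_ids) {
      set.seed(derive_seed(cfg$seed, i, 6L))
      sample(1:2, 1, prob = c(5, 3))
    } else 0L
    second <- if (n_second > 0) {
      lapply(seq_len(n_second), function(d)
        apply_random_events(p$ancestor, cfg, arms,
                            stats::rpois(1, cfg$lambda_div)))
    } else list()
    second_purity <- if (n_second > 0)
      draw_purity(cfg, p$purity_mean, n_second)
    else numeric(0)
    deposits <- c(p$deposits, second)
    purity <- c(p$purity, second_purity)
    resection <- c(rep(1L, n_dep), rep(2L, n_second))
    set.seed(derive_seed(cfg$seed, i, 1L))
    for (d in seq_along(deposits)) {
      sid <- sprintf("%s_M%d", p$patient, d)
      vals[[sid]] <- render_lrr(deposits[[d]], purity[d], cfg$noise_sd,
                                probes, cfg$min_lrr)
      seg <- deposits[[d]]
      seg_rows[[sid]] <- data.frame(sample = sid, seg,
                                    stringsAsFactors = FALSE)
      meta_rows[[sid]] <- data.frame(sample = sid, rho = purity[d],
                                     psi = profile_ploidy(deposits[[d]]),
                                     stringsAsFactors = FALSE)
      clin_rows[[sid]] <- data.frame(
        patient = p$patient, sample = sid, resection = resection[d],
        synchronous = p$covariates$synchronous, chemo = p$covariates$chemo,
        tp53 = p$covariates$tp53, age = p$covariates$age,
        sex = p$covariates$sex,
        ccf = if (stats::runif(1) < cfg$ccf_fail_prob) NA_real_
        else purity[d],
        stringsAsFactors = FALSE)
    }
  }
  values <- do.call(cbind, vals)
  rownames(values) <- probes$marker
  lrr <- lrr_matrix(probes, values, cfg$genome)

  clinical <- do.call(rbind, clin_rows)
  het_true <- vapply(pats, function(p) p$true_divergence, numeric(1))
  pfs <- simulate_survival(het_true, cfg$pfs_median_months, cfg$pfs_hr,
                           cfg$censoring, derive_seed(cfg$seed, 0L, 2L))
  os <- simulate_survival(het_true, cfg$os_median_months, cfg$os_hr,
                          cfg$censoring, derive_seed(cfg$seed, 0L, 3L))
  idx <- match(clinical$patient,
               vapply(pats, function(p) p$patient, character(1)))
  clinical$pfs_time <- pfs$time[idx]
  clinical$pfs_event <- pfs$event[idx]
  clinical$os_time <- os$time[idx]
  clinical$os_event <- os$event[idx]
  rownames(clinical) <- NULL

  truth <- allele_profiles(do.call(rbind, seg_rows)[
    , c("sample", "chrom", "start", "end", "nA", "nB")],
    do.call(rbind, meta_rows))
  list(lrr = lrr, truth = truth, clinical = as_cohort_table(clinical),
       patients = pats, probes = probes)
}

#' Write a simulated cohort to disk
#'
#' Emits `lrr.tsv` (probe-level LRR), `allele_truth.tsv` (allele-specific
#' truth profiles with purity/ploidy), `clinical.csv` and `truth.tsv`
#' (per-patient true divergence and per-deposit aberrant / cnLOH
#' fractions), all readable by the package's readers. Output is
#' byte-identical for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if absent).
#' @return the cohort list from [simulate_cohort()], invisibly.
#' @export
emit_cohort <- function(cfg, dir) {
  cohort <- simulate_cohort(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_lrr_table(cohort$lrr, file.path(dir, "lrr.tsv"))
  write_allele_profiles(cohort$truth, file.path(dir, "allele_truth.tsv"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- do.call(rbind, lapply(cohort$patients, function(p)
    data.frame(patient = p$patient, n_deposits = length(p$deposits),
               true_divergence = p$true_divergence,
               mean_aberrant_fraction = mean(p$aberrant_fraction),
               mean_cnloh_fraction = mean(p$cnloh_fraction),
               stringsAsFactors = FALSE)))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(cohort)
}
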