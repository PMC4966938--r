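#' Cross-sample variance filter on atomic segments
#'
#' Retains atoms whose copy number estimate variance across all samples in
#' the analysis set exceeds `cutoff` (strict; sample variance, denominator
#' n - 1). The filter restricts heterogeneity scoring and clustering to the
#' informative part of the genome; atoms that are identical in every
#' sample carry no signal and only dilute distances.
#'
#' @param x an `atomic_matrix` with >= 2 samples.
#' @param cutoff variance cutoff (default 0.03); `NA` or `"none"` disables
#'   filtering.
#' @return the filtered `atomic_matrix` (attribute `retained_fraction`
#'   records the surviving fraction of atoms).
#' @export
variance_filter <- function(x, cutoff = 0.03) {
  stopifnot(inherits(x, "atomic_matrix"))
  if (is.character(cutoff) && identical(cutoff, "none")) cutoff <- NA
  if (is.na(cutoff)) {
    attr(x, "retained_fraction") <- 1
    return(x)
  }
  if (length(x$samples) < 2L) stop("variance filter needs >= 2 samples")
  v <- apply(x$estimates, 1, stats::var)
  keep <- v > cutoff
  if (!any(keep))
    stop("no atoms exceed the variance cutoff; consider cutoff = \"none\"")
  out <- subset_atoms(x, atoms = keep)
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Euclidean distance between two copy number profiles
#'
#' The square root of the summed squared differences in copy number
#' estimate over all atoms; atoms are unweighted dimensions (no bp or
#' probe weighting), so the score grows with the number of differing
#' atoms as well as the size of each difference.
#'
#' @param a,b numeric vectors of atom estimates on the same atoms.
#' @return non-negative distance.
#' @export
pairwise_euclidean <- function(a, b) {
  if (length(a) != length(b)) stop("profiles have different numbers of atoms")
  sqrt(sum((a - b)^2))
}

het_result <- function(patient, score, method, n_samples, n_pairs,
                       variance_cutoff, n_atoms, reason = NA_character_) {
  structure(list(patient = patient, score = score, method = method,
                 n_samples = n_samples, n_pairs = n_pairs,
                 variance_cutoff = variance_cutoff, n_atoms = n_atoms,
                 reason = reason),
            class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("patient %s: %s heterogeneity = %s (%d samples, %d pairs, %d atoms)\n",
              x$patient, x$method,
              ifelse(is.na(x$score), paste0("absent [", x$reason, "]"),
                     format(x$score)),
              x$n_samples, x$n_pairs,
              ifelse(is.na(x$n_atoms), 0L, x$n_atoms)))
  invisible(x)
}

#' Intra-patient inter-metastatic heterogeneity (Euclidean score)
#'
#' The mean pairwise Euclidean distance of atomic copy number estimates
#' over all unordered pairs of a patient's deposits, computed on the
#' variance-filtered atom set. The variance is taken across all samples in
#' the supplied matrix (the analysis set, typically all first-resection
#' deposits of the cohort), not per patient. Patients with fewer than two
#' deposits have no defined score and are reported as absent.
#'
#' @param x an `atomic_matrix` for the full analysis set.
#' @param samples the patient's sample ids (first-resection deposits).
#' @param variance_cutoff variance filter cutoff (0.03 default; 0.05 and
#'   `"none"` are the robustness variants).
#' @param patient patient id used for labelling.
#' @return a `het_result`.
#' @export
patient_heterogeneity <- function(x, samples, variance_cutoff = 0.03,
                                  patient = NA_character_) {
  stopifnot(inherits(x, "atomic_matrix"), all(samples %in% x$samples))
  if (length(samples) < 2L)
    return(het_result(patient, NA_real_, "euclidean", length(samples), 0L,
                      variance_cutoff, NA_integer_,
                      reason = "fewer than two deposits"))
  xf <- variance_filter(x, variance_cutoff)
  e <- xf$estimates[, samples, drop = FALSE]
  pairs <- utils::combn(length(samples), 2)
  d <- apply(pairs, 2, function(p) pairwise_euclidean(e[, p[1]], e[, p[2]]))
  het_result(patient, mean(d), "euclidean", length(samples), ncol(pairs),
             variance_cutoff, nrow(xf$atoms))
}

#' Heterogeneity as the proportion of the genome with different copy numbers
#'
#' For each unordered pair of deposits, the summed bp length of atoms whose
#' copy number estimates differ by more than `diff_cutoff` (strict),
#' divided by the total bp of all atoms and expressed in per cent; the
#' patient score is the mean over pairs. No variance pre-filter is applied;
#' the bp weighting makes this the length-aware counterpart of the
#' Euclidean score.
#'
#' @param x an `atomic_matrix`.
#' @param samples the patient's sample ids.
#' @param diff_cutoff difference threshold on estimates (default 0.1).
#' @param patient patient id for labelling.
#' @return a `het_result` with `score` in per cent of base pairs.
#' @export
proportion_genome_different <- function(x, samples, diff_cutoff = 0.1,
                                        patient = NA_character_) {
  stopifnot(inherits(x, "atomic_matrix"), all(samples %in% x$samples))
  if (length(samples) < 2L)
    return(het_result(patient, NA_real_, "proportion_genome",
                      length(samples), 0L, NA, NA_integer_,
                      reason = "fewer than two deposits"))
  e <- x$estimates[, samples, drop = FALSE]
  len <- x$atoms$length_bp
  total <- sum(len)
  pairs <- utils::combn(length(samples), 2)
  pct <- apply(pairs, 2, function(p) {
    diff <- abs(e[, p[1]] - e[, p[2]])
    100 * sum(len[diff > diff_cutoff]) / total
  })
  het_result(patient, mean(pct), "proportion_genome", length(samples),
             ncol(pairs), NA, nrow(x$atoms))
}

#' Longitudinal heterogeneity between sequential resections
#'
#' Mean Euclidean distance over all cross-resection pairs (each
#' first-resection deposit against each second-resection deposit) of one
#' patient, on the variance-filtered atom set. Pairs within a resection
#' are not included by default; `all_pairs = TRUE` switches to all
#' unordered pairs in the union of the two resections.
#'
#' @param x an `atomic_matrix` containing both resections' samples.
#' @param first_samples,second_samples sample ids per resection.
#' @param variance_cutoff variance filter cutoff.
#' @param all_pairs use all pairs in the union instead of cross pairs only.
#' @param patient patient id for labelling.
#' @return a `het_result`.
#' @export
longitudinal_heterogeneity <- function(x, first_samples, second_samples,
                                       variance_cutoff = 0.03,
                                       all_pairs = FALSE,
                                       patient = NA_character_) {
  stopifnot(inherits(x, "atomic_matrix"))
  n1 <- length(first_samples); n2 <- length(second_samples)
  if (n1 < 1L || n2 < 1L)
    return(het_result(patient, NA_real_, "euclidean", n1 + n2, 0L,
                      variance_cutoff, NA_integer_,
                      reason = "a resection has no samples"))
  xf <- variance_filter(x, variance_cutoff)
  if (all_pairs) {
    smp <- c(first_samples, second_samples)
    pr <- utils::combn(smp, 2)
  } else {
    pr <- rbind(rep(first_samples, each = n2), rep(second_samples, n1))
  }
  d <- apply(pr, 2, function(p)
    pairwise_euclidean(xf$estimates[, p[1]], xf$estimates[, p[2]]))
  het_result(patient, mean(d), "euclidean", n1 + n2, ncol(pr),
             variance_cutoff, nrow(xf$atoms))
}

#' Ploidy-adjusted heterogeneity from allele-specific profiles
#'
#' The Euclidean score computed on absolute total copy numbers (nA + nB)
#' divided by each sample's ploidy, on the atomic partition defined by the
#' union of the allele-specific segment breakpoints; no variance filter.
#' Dividing by ploidy removes whole-genome scaling, so a diploid profile
#' and its genome-doubled copy are at distance zero.
#'
#' @param profiles an `allele_profiles` object.
#' @param samples the patient's sample ids; samples without a profile are
#'   dropped (pairs involving them are skipped).
#' @param patient patient id for labelling.
#' @return a `het_result`.
#' @export
ploidy_adjusted_heterogeneity <- function(profiles, samples,
                                          patient = NA_character_) {
  stopifnot(inherits(profiles, "allele_profiles"))
  have <- intersect(samples, profiles$samples$sample)
  if (length(have) < length(samples))
    message(length(samples) - length(have),
            " sample(s) without allele-specific profile skipped")
  if (length(have) < 2L)
    return(het_result(patient, NA_real_, "euclidean_ploidy_adjusted",
                      length(have), 0L, NA, NA_integer_,
                      reason = "fewer than two profiled deposits"))
  seg <- profiles$segments[profiles$segments$sample %in% have, , drop = FALSE]
  seg$estimate <- seg$nA + seg$nB
  seg$n_probes <- 1L
  atoms <- atomic_segments(seg)
  psi <- profiles$samples$psi[match(have, profiles$samples$sample)]
  e <- sweep(atoms$estimates[, have, drop = FALSE], 2, psi, "/")
  pairs <- utils::combn(length(have), 2)
  d <- apply(pairs, 2, function(p) pairwise_euclidean(e[, p[1]], e[, p[2]]))
  het_result(patient, mean(d), "euclidean_ploidy_adjusted", length(have),
             ncol(pairs), NA, nrow(atoms$atoms))
}

#' Patient-wise diversity in cancer cell fraction
#'
#' Mean absolute pairwise difference of the cancer cell fractions (purity
#' estimates) over all unordered pairs of a patient's deposits; samples
#' with a missing fraction are excluded.
#'
#' @param cohort a `cohort_table` with a `ccf` column.
#' @param patient patient id.
#' @param resection resection index (default 1).
#' @return numeric diversity, or `NA` if fewer than two usable samples.
#' @export
ccf_diversity <- function(cohort, patient, resection = 1) {
  smp <- cohort[cohort$patient == patient & cohort$resection %in% resection, ]
  ccf <- smp$ccf[!is.na(smp$ccf)]
  if (length(ccf) < 2L) return(NA_real_)
  pairs <- utils::combn(ccf, 2)
  mean(abs(pairs[1, ] - pairs[2, ]))
}

#' Heterogeneity scores for every patient of a cohort
#'
#' @param x an `atomic_matrix` over the analysis set (typically all
#'   first-resection deposits).
#' @param cohort a `cohort_table`.
#' @param method `"euclidean"` or `"proportion_genome"`.
#' @param variance_cutoff filter cutoff for the Euclidean score.
#' @param diff_cutoff difference threshold for the proportion score.
#' @return data frame `patient`, `score`, `n_samples`, `n_pairs`.
#' @export
cohort_heterogeneity <- function(x, cohort, method = c("euclidean",
                                                       "proportion_genome"),
                                 variance_cutoff = 0.03, diff_cutoff = 0.1) {
  method <- match.arg(method)
  patients <- unique(cohort$patient)
  rows <- lapply(patients, function(p) {
    smp <- intersect(patient_samples(cohort, p), x$samples)
    r <- if (method == "euclidean")
      patient_heterogeneity(x, smp, variance_cutoff, patient = p)
    else
      proportion_genome_different(x, smp, diff_cutoff, patient = p)
    data.frame(patient = p, score = r$score, n_samples = r$n_samples,
               n_pairs = r$n_pairs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
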