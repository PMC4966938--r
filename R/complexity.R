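#' Genomic complexity of a copy-number profile
#'
#' The proportion (per cent of base pairs) of the analyzed genome with
#' aberrant copy numbers: segments whose estimate exceeds `+cutoff` or
#' falls below `-cutoff` (strict), relative to the total bp of all
#' segments in the profile. This is a fraction-of-genome-altered measure
#' of chromosomal instability; the denominator is the retained
#' (post-filter) autosomal territory, since excluded regions carry no
#' calls.
#'
#' @param segments segment data frame for one sample (`chrom`, `start`,
#'   `end`, `estimate`).
#' @param cutoff aberration threshold (default 0.1).
#' @return per cent in [0, 100].
#' @export
genomic_complexity <- function(segments, cutoff = 0.1) {
  if (nrow(segments) == 0L) stop("empty profile")
  len <- segments$end - segments$start + 1
  calls <- call_aberrations(segments$estimate, cutoff)
  100 * sum(len[calls != "neutral"]) / sum(len)
}

#' Patient-wise genomic complexity
#'
#' Arithmetic mean of the sample-level complexities over a patient's
#' first-resection deposits.
#'
#' @param segments segment data frame containing the patient's samples.
#' @param samples the patient's first-resection sample ids.
#' @param cutoff aberration threshold.
#' @return per cent in [0, 100].
#' @export
patient_complexity <- function(segments, samples, cutoff = 0.1) {
  stopifnot(length(samples) >= 1L)
  mean(vapply(samples, function(s)
    genomic_complexity(segments[segments$sample == s, , drop = FALSE],
                       cutoff), numeric(1)))
}

#' Complexity for every sample and patient of a cohort
#'
#' @param segments cohort segment data frame.
#' @param cohort a `cohort_table`.
#' @param cutoff aberration threshold.
#' @return list with `samples` (data frame `sample`, `percent`) and
#'   `patients` (data frame `patient`, `percent`, mean over
#'   first-resection deposits).
#' @export
cohort_complexity <- function(segments, cohort, cutoff = 0.1) {
  smp <- unique(segments$sample)
  per_sample <- data.frame(sample = smp,
                           percent = vapply(smp, function(s)
                             genomic_complexity(
                               segments[segments$sample == s, , drop = FALSE],
                               cutoff), numeric(1)),
                           stringsAsFactors = FALSE, row.names = NULL)
  patients <- unique(cohort$patient)
  per_patient <- data.frame(patient = patients,
                            percent = vapply(patients, function(p) {
                              s <- intersect(patient_samples(cohort, p), smp)
                              if (length(s) == 0L) return(NA_real_)
                              mean(per_sample$percent[match(s, per_sample$sample)])
                            }, numeric(1)),
                            stringsAsFactors = FALSE, row.names = NULL)
  list(samples = per_sample, patients = per_patient)
}

#' Patient-wise aberration frequency per atomic segment
#'
#' For each atom, the fraction of patients with at least one deposit
#' called as a gain, and separately the fraction with at least one deposit
#' called as a loss. A patient whose deposits include both a gained and a
#' lost copy of the atom counts once in each frequency.
#'
#' @param x an `atomic_matrix`.
#' @param cohort a `cohort_table` mapping samples to patients.
#' @param cutoff aberration threshold (default 0.1).
#' @return data frame of the atoms with `gain_freq` and `loss_freq`.
#' @export
patientwise_aberration_frequency <- function(x, cohort, cutoff = 0.1) {
  stopifnot(inherits(x, "atomic_matrix"))
  calls <- call_aberrations(x$estimates, cutoff)
  pat <- cohort$patient[match(x$samples, cohort$sample)]
  if (anyNA(pat)) stop("samples missing from the cohort table: ",
                       paste(x$samples[is.na(pat)][1:3], collapse = ", "))
  patients <- unique(pat)
  gain <- loss <- matrix(FALSE, nrow(x$atoms), length(patients))
  for (k in seq_along(patients)) {
    cols <- which(pat == patients[k])
    gain[, k] <- rowSums(calls[, cols, drop = FALSE] == "gain") > 0
    loss[, k] <- rowSums(calls[, cols, drop = FALSE] == "loss") > 0
  }
  out <- x$atoms
  out$gain_freq <- rowMeans(gain)
  out$loss_freq <- rowMeans(loss)
  out
}

#' Copy-neutral LOH fraction of an allele-specific profile
#'
#' Per cent of base pairs in segments with allele copies {0, 2}: two total
#' copies (copy neutral) but complete loss of one parental allele. A
#' segment such as (0, 3) is LOH but not copy neutral and does not count.
#'
#' @param profiles an `allele_profiles` object.
#' @param sample sample id.
#' @return per cent in [0, 100].
#' @export
cnloh_fraction <- function(profiles, sample) {
  stopifnot(inherits(profiles, "allele_profiles"))
  seg <- profiles$segments[profiles$segments$sample == sample, , drop = FALSE]
  if (nrow(seg) == 0L) stop("no segments for sample ", sample)
  len <- seg$end - seg$start + 1
  is_cnloh <- (pmin(seg$nA, seg$nB) == 0L) & (pmax(seg$nA, seg$nB) == 2L)
  100 * sum(len[is_cnloh]) / sum(len)
}
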