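#' Readers and writers for the pipeline's tabular formats
#'
#' All files are plain tab- or comma-delimited text with '.' as the decimal
#' separator and no thousands separators. Genomic coordinates are 1-based
#' inclusive base pairs, matching array annotation conventions; interval
#' lengths are therefore end - start + 1.
#'
#' @name methet-io
NULL

# full-precision numeric formatting so that write -> read is bit-exact
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a probe-level log R ratio (LRR) table
#'
#' The file is tab-delimited with header columns `marker`, `chrom`, `pos`,
#' optionally `class` (one of `SNP`, `CN`, `control`), followed by one
#' numeric column per sample. Rows on chromosomes absent from `genome`
#' (e.g. allosomes) are dropped with a message. Probes are sorted by
#' genomic position; sample column order is preserved.
#'
#' @param path file path.
#' @param genome a `genome_build`; rows outside it are excluded.
#' @return an `lrr_matrix`: list with `probes` (data frame: `marker`,
#'   `chrom`, `pos`, `class`), `samples` (character) and `values`
#'   (numeric matrix, probes x samples; `NA` allowed).
#' @export
read_lrr_table <- function(path, genome = genome_hg19()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("LRR table must have columns marker, chrom, pos")
  has_class <- "class" %in% names(df)
  sample_cols <- setdiff(names(df), c(need, "class"))
  if (length(sample_cols) == 0L) stop("LRR table has no sample columns")

  keep <- df$chrom %in% genome$chrom
  if (any(!keep)) {
    message(sum(!keep), " probe(s) on non-autosomal/unknown chromosomes excluded")
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no probes remain after chromosome filtering")
  if (anyDuplicated(df$marker))
    stop("duplicate marker ids in LRR table: ",
         paste(unique(df$marker[duplicated(df$marker)])[1:3], collapse = ", "))

  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) stop("non-integer probe position at row ", which(is.na(pos))[1])
  vals <- matrix(NA_real_, nrow(df), length(sample_cols),
                 dimnames = list(df$marker, sample_cols))
  for (s in sample_cols) {
    raw <- df[[s]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw) & !(raw %in% c("NA", "", "NaN")))
    if (length(bad))
      stop("non-numeric value in column '", s, "', row ", bad[1],
           " (marker ", df$marker[bad[1]], ")")
    vals[, s] <- v
  }
  probes <- data.frame(marker = df$marker, chrom = df$chrom, pos = pos,
                       class = if (has_class) df$class else "SNP",
                       stringsAsFactors = FALSE)
  ord <- genome_order(genome, probes$chrom, probes$pos)
  probes <- probes[ord, , drop = FALSE]
  rownames(probes) <- NULL
  vals <- vals[ord, , drop = FALSE]
  lrr_matrix(probes, vals, genome)
}

#' Construct an `lrr_matrix` from a probe table and value matrix
#'
#' @param probes data frame with `marker`, `chrom`, `pos` and optionally
#'   `class` columns, sorted by genome order.
#' @param values numeric matrix, probes x samples, with sample column names.
#' @param genome the `genome_build` the probes live on.
#' @return an `lrr_matrix` object.
#' @export
lrr_matrix <- function(probes, values, genome = genome_hg19()) {
  stopifnot(nrow(probes) == nrow(values))
  if (is.null(colnames(values))) stop("values must have sample column names")
  if (is.null(probes$class)) probes$class <- "SNP"
  x <- list(probes = probes, samples = colnames(values), values = values,
            genome = genome)
  class(x) <- "lrr_matrix"
  x
}

#' @export
print.lrr_matrix <- function(x, ...) {
  cat("lrr_matrix:", nrow(x$probes), "probes x", length(x$samples),
      "samples on", length(unique(x$probes$chrom)), "chromosomes\n")
  invisible(x)
}

#' Write an LRR table
#'
#' Inverse of [read_lrr_table()]; numeric values are printed at full
#' precision so the round trip is exact.
#'
#' @param x an `lrr_matrix`.
#' @param path output file path.
#' @export
write_lrr_table <- function(x, path) {
  stopifnot(inherits(x, "lrr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("marker", "chrom", "pos", "class", x$samples),
                   collapse = "\t"), con)
  body <- cbind(x$probes$marker, x$probes$chrom, x$probes$pos, x$probes$class,
                apply(x$values, 2, fmt_num))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write segmented copy-number profiles
#'
#' BED-like tab-delimited file with columns `sample`, `chrom`, `start`,
#' `end`, `n_probes`, `estimate` (1-based inclusive coordinates, estimates
#' at full precision).
#'
#' @param segments data frame of segments (as produced by [segment_profiles()]).
#' @param path output file path.
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sample\tchrom\tstart\tend\tn_probes\testimate", con)
  writeLines(paste(segments$sample, segments$chrom, segments$start,
                   segments$end, segments$n_probes, fmt_num(segments$estimate),
                   sep = "\t"), con)
  invisible(path)
}

#' Read segmented copy-number profiles
#'
#' @param path file written by [write_segments()].
#' @return data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `n_probes`, `estimate`.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(sample = "character",
                                         chrom = "character"))
  validate_segments(df)
  df
}

validate_segments <- function(segments) {
  need <- c("sample", "chrom", "start", "end", "n_probes", "estimate")
  if (!all(need %in% names(segments)))
    stop("segment table must have columns ", paste(need, collapse = ", "))
  if (any(segments$start > segments$end))
    stop("segment with start > end")
  # overlap check within sample x chromosome
  key <- split(segments, list(segments$sample, segments$chrom), drop = TRUE)
  for (grp in key) {
    if (nrow(grp) < 2L) next
    grp <- grp[order(grp$start), ]
    if (any(grp$start[-1] <= grp$end[-nrow(grp)]))
      stop("overlapping segments for sample ", grp$sample[1],
           " on chromosome ", grp$chrom[1])
  }
  invisible(segments)
}

#' Read a clinical table
#'
#' CSV with header columns `patient`, `sample`, `resection` (1 or 2),
#' `synchronous` (0/1, 1 = detected with the primary tumour), `chemo`
#' (0/1 previous chemotherapy exposure), `tp53`
#' (`wildtype`/`mutated`/`heterogeneous`), `age`, `sex` (`F`/`M`), `ccf`
#' (cancer cell fraction in (0,1], may be `NA`), `pfs_time`, `pfs_event`,
#' `os_time`, `os_event` (times in months from start of treatment for the
#' liver metastases). A missing event flag is parsed as censored, with a
#' warning.
#'
#' @param path CSV file path.
#' @return a `cohort_table`: data frame with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = c(patient = "character",
                                       sample = "character"))
  as_cohort_table(df)
}

#' Validate a clinical data frame as a cohort table
#'
#' @param df data frame in [read_clinical()] layout.
#' @return a validated `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  need <- c("patient", "sample", "resection")
  if (!all(need %in% names(df)))
    stop("clinical table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample)) {
    dup <- unique(df$sample[duplicated(df$sample)])
    two <- vapply(dup, function(s)
      length(unique(df$patient[df$sample == s])) > 1L, logical(1))
    if (any(two))
      stop("sample mapped to two patients: ", dup[which(two)[1]])
    stop("duplicate sample rows: ", dup[1])
  }
  for (ev in c("pfs_event", "os_event")) {
    if (!ev %in% names(df)) next
    if (anyNA(df[[ev]])) {
      warning(sum(is.na(df[[ev]])), " missing ", ev,
              " flag(s) parsed as censored")
      df[[ev]][is.na(df[[ev]])] <- 0L
    }
  }
  for (tm in c("pfs_time", "os_time")) {
    if (tm %in% names(df) && any(df[[tm]] < 0, na.rm = TRUE))
      stop("negative ", tm)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Patient-level view of a cohort table
#'
#' @param cohort a `cohort_table`.
#' @return data frame with one row per patient and its sample count per
#'   resection; per-patient covariates are taken from the first sample row.
#' @export
cohort_patients <- function(cohort) {
  sp <- split(seq_len(nrow(cohort)), cohort$patient)
  rows <- lapply(names(sp), function(p) {
    i <- sp[[p]]
    first <- cohort[i[1], , drop = FALSE]
    data.frame(patient = p,
               n_samples_r1 = sum(cohort$resection[i] == 1),
               n_samples_r2 = sum(cohort$resection[i] == 2),
               first[setdiff(names(first),
                             c("patient", "sample", "resection", "ccf"))],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Samples of a patient at a given resection
#'
#' @param cohort a `cohort_table`.
#' @param patient patient id.
#' @param resection resection index (default 1, the first liver resection).
#' @return character vector of sample ids.
#' @export
patient_samples <- function(cohort, patient, resection = 1) {
  cohort$sample[cohort$patient == patient & cohort$resection %in% resection]
}

#' Write / read allele-specific integer copy-number profiles
#'
#' Tab-delimited columns `sample`, `chrom`, `start`, `end`, `nA`, `nB`,
#' `rho` (purity), `psi` (ploidy); purity and ploidy are per-sample
#' constants repeated on each row.
#'
#' @param profiles an `allele_profiles` object (see [allele_profiles()]).
#' @param path file path.
#' @export
write_allele_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "allele_profiles"))
  seg <- profiles$segments
  meta <- profiles$samples
  rho <- meta$rho[match(seg$sample, meta$sample)]
  psi <- meta$psi[match(seg$sample, meta$sample)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sample\tchrom\tstart\tend\tnA\tnB\trho\tpsi", con)
  writeLines(paste(seg$sample, seg$chrom, seg$start, seg$end, seg$nA, seg$nB,
                   fmt_num(rho), fmt_num(psi), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_allele_profiles
#' @return `read_allele_profiles()` returns an `allele_profiles` object.
#' @export
read_allele_profiles <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(sample = "character",
                                         chrom = "character"))
  meta <- unique(df[, c("sample", "rho", "psi")])
  if (anyDuplicated(meta$sample))
    stop("inconsistent rho/psi within a sample")
  allele_profiles(df[, c("sample", "chrom", "start", "end", "nA", "nB")], meta)
}

#' Construct an allele-specific profile set
#'
#' @param segments data frame `sample`, `chrom`, `start`, `end`, `nA`, `nB`
#'   (integer allele copies, non-negative, non-overlapping per sample).
#' @param samples data frame `sample`, `rho` (purity in (0,1]), `psi`
#'   (ploidy, mean copies per locus).
#' @return an `allele_profiles` object.
#' @export
allele_profiles <- function(segments, samples) {
  if (any(segments$nA < 0) || any(segments$nB < 0))
    stop("allele copy numbers must be non-negative")
  if (any(samples$rho <= 0 | samples$rho > 1))
    stop("purity rho must lie in (0, 1]")
  seg <- segments
  seg$n_probes <- 0L
  seg$estimate <- 0
  validate_segments(seg)  # reuse overlap/ordering checks
  x <- list(segments = segments, samples = samples)
  class(x) <- "allele_profiles"
  x
}
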