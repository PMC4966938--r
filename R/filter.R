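#' Aberration frequency per atomic segment
#'
#' Fraction of samples whose copy number estimate exceeds the aberration
#' cutoff in absolute value (gains and losses both count), per atom. Used
#' to identify regions recurrently "aberrant" in non-cancer samples,
#' which reflect technical artefacts rather than somatic events.
#'
#' @param x an `atomic_matrix` (>= 1 sample).
#' @param cutoff aberration threshold on the estimate (default 0.1).
#' @return numeric vector of per-atom frequencies in [0, 1].
#' @export
region_aberration_frequency <- function(x, cutoff = 0.1) {
  stopifnot(inherits(x, "atomic_matrix"))
  if (length(x$samples) == 0L) stop("empty cohort")
  rowMeans(abs(x$estimates) > cutoff)
}

#' Build a recurrent-aberration region blacklist from non-cancer cohorts
#'
#' Each cohort is a segment data frame (samples segmented on the shared
#' probe panel). Atomic segments are formed across all cohorts jointly;
#' a region is blacklisted when its aberration frequency is strictly
#' higher than `freq_threshold` in EVERY cohort (intersection rule), and
#' adjacent blacklisted atoms are merged into maximal intervals.
#'
#' @param cohorts list (length >= 1) of segment data frames.
#' @param freq_threshold frequency cutoff (default 0.10, strict `>`).
#' @param cutoff aberration threshold on the estimate (default 0.1).
#' @return a `region_blacklist`: data frame `chrom`, `start`, `end` with
#'   a `provenance` attribute holding the per-cohort atom frequencies.
#' @export
build_blacklist <- function(cohorts, freq_threshold = 0.10, cutoff = 0.1) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  tagged <- lapply(seq_along(cohorts), function(k) {
    seg <- cohorts[[k]]
    seg$sample <- paste0("c", k, ":", seg$sample)
    seg
  })
  atoms <- tryCatch(atomic_segments(do.call(rbind, tagged)),
                    error = function(e)
                      stop("cohorts on mismatched panels: ",
                           conditionMessage(e)))
  freqs <- vapply(seq_along(cohorts), function(k) {
    cols <- grep(paste0("^c", k, ":"), atoms$samples)
    region_aberration_frequency(subset_atoms(atoms,
                                             atoms$samples[cols]), cutoff)
  }, numeric(nrow(atoms$atoms)))
  freqs <- matrix(freqs, nrow = nrow(atoms$atoms))
  colnames(freqs) <- paste0("cohort", seq_along(cohorts))
  bad <- rowSums(freqs > freq_threshold) == length(cohorts)
  regions <- merge_adjacent(atoms$atoms[bad, c("chrom", "start", "end"),
                                        drop = FALSE])
  structure(regions, provenance = cbind(atoms$atoms, freqs),
            class = c("region_blacklist", "data.frame"))
}

merge_adjacent <- function(regions) {
  if (nrow(regions) == 0L) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
    return(out)
  }
  regions <- regions[order(regions$chrom, regions$start), ]
  out <- regions[1, , drop = FALSE]
  if (nrow(regions) > 1L) for (i in 2:nrow(regions)) {
    last <- nrow(out)
    if (regions$chrom[i] == out$chrom[last] &&
        regions$start[i] <= out$end[last] + 1) {
      out$end[last] <- max(out$end[last], regions$end[i])
    } else {
      out <- rbind(out, regions[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Total base pairs covered by a blacklist
#'
#' @param blacklist a `region_blacklist`.
#' @return total bp.
#' @export
blacklist_bp <- function(blacklist) {
  if (nrow(blacklist) == 0L) return(0)
  sum(blacklist$end - blacklist$start + 1)
}

#' Apply probe-level exclusion filters to an LRR matrix
#'
#' Removes, in this order: control probes, duplicate probes (probes at an
#' already-seen (chrom, pos) locus; the first in genomic order is kept),
#' and probes whose position lies inside a blacklisted region (closed
#' interval). Allosomal probes are already excluded by the genome model at
#' load time. The count removed in each category is reported. Filtering is
#' idempotent.
#'
#' @param x an `lrr_matrix`.
#' @param blacklist optional `region_blacklist`.
#' @param drop_control drop probes with class `control` (default TRUE).
#' @param drop_duplicates drop duplicate-position probes (default TRUE).
#' @return the filtered `lrr_matrix` (possibly empty, with a warning).
#' @export
apply_filters <- function(x, blacklist = NULL, drop_control = TRUE,
                          drop_duplicates = TRUE) {
  stopifnot(inherits(x, "lrr_matrix"))
  keep <- rep(TRUE, nrow(x$probes))
  n_control <- n_dup <- n_black <- 0L
  if (drop_control) {
    ctrl <- x$probes$class == "control"
    n_control <- sum(ctrl & keep)
    keep <- keep & !ctrl
  }
  if (drop_duplicates) {
    dup <- duplicated(paste(x$probes$chrom, x$probes$pos))
    n_dup <- sum(dup & keep)
    keep <- keep & !dup
  }
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    inb <- rep(FALSE, nrow(x$probes))
    for (i in seq_len(nrow(blacklist))) {
      inb <- inb | (x$probes$chrom == blacklist$chrom[i] &
                      x$probes$pos >= blacklist$start[i] &
                      x$probes$pos <= blacklist$end[i])
    }
    n_black <- sum(inb & keep)
    keep <- keep & !inb
  }
  message(sprintf("probe filters: %d control, %d duplicate, %d blacklisted removed; %d retained",
                  n_control, n_dup, n_black, sum(keep)))
  if (!any(keep)) warning("all probes removed by filters")
  out <- lrr_matrix(x$probes[keep, , drop = FALSE],
                    x$values[keep, , drop = FALSE], x$genome)
  rownames(out$probes) <- NULL
  out
}
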