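#' Segmentation parameters
#'
#' Defaults follow the published analysis settings for full-density SNP
#' array data: breakpoint penalty `gamma = 100`, minimum `kmin = 5` probes
#' per segment, and winsorization in a centered window of 25 probes at 2.5
#' MAD units. For sparser marker panels (e.g. the scaled synthetic genome)
#' `gamma` should be reduced in proportion to the number of probes an event
#' spans, since the penalty competes with a within-segment error sum that
#' grows with probe count.
#'
#' @param gamma penalty per additional segment (> 0).
#' @param kmin minimum probes per segment (>= 1).
#' @param winsor_k winsorization window size in probes (odd).
#' @param winsor_tau clamp width in scaled-MAD units.
#' @return a `seg_params` list.
#' @export
seg_params <- function(gamma = 100, kmin = 5, winsor_k = 25, winsor_tau = 2.5) {
  stopifnot(gamma > 0, kmin >= 1, winsor_k >= 1, winsor_k %% 2 == 1,
            winsor_tau > 0)
  structure(list(gamma = gamma, kmin = kmin, winsor_k = winsor_k,
                 winsor_tau = winsor_tau), class = "seg_params")
}

#' Winsorize a vector of log-ratios
#'
#' Clamps each value to the running median plus/minus `tau` running MADs
#' (MAD scaled by 1.4826), computed in a centered window of `k` probes,
#' truncated at the ends of the vector (one chromosome at a time). Limits
#' the influence of single-probe outliers on the segmentation without
#' moving values that are locally typical.
#'
#' @param values numeric vector (one chromosome, one sample).
#' @param k window size in probes (odd).
#' @param tau clamp width in scaled-MAD units.
#' @return numeric vector of the same length.
#' @export
winsorize <- function(values, k = 25, tau = 2.5) {
  stopifnot(is.numeric(values), k >= 1, k %% 2 == 1, tau > 0)
  if (length(values) == 0L) return(values)
  .winsorize_window(as.numeric(values), as.integer(k), as.double(tau))
}

# probe territory boundaries on one chromosome: each probe owns the interval
# from the midpoint to its left neighbour to the midpoint to its right
# neighbour (chromosome-end probes own up to their own position), so that
# every sample's segments tile the identical covered territory.
probe_bounds <- function(pos) {
  m <- length(pos)
  if (m == 1L) return(data.frame(left = pos, right = pos))
  mid <- floor((pos[-m] + pos[-1]) / 2)
  data.frame(left = c(pos[1], mid + 1), right = c(mid, pos[m]))
}

#' Exact single-sample piecewise constant fitting (PCF)
#'
#' Finds the exact minimizer of
#' \deqn{\sum_{segments} \sum_{i \in seg} (y_i - \bar y_{seg})^2 +
#'       \gamma (\#segments - 1)}
#' subject to every segment containing at least `kmin` probes, by dynamic
#' programming over breakpoint positions (one chromosome at a time). The
#' segment estimate is the arithmetic mean of its member probes; these
#' means are the copy number estimates used by all downstream statistics.
#'
#' @param values numeric vector of (winsorized) log-ratios.
#' @param positions integer bp positions of the probes (sorted ascending).
#' @param params a [seg_params()] object.
#' @return data frame `start`, `end` (1-based inclusive bp of the probe
#'   territory), `n_probes`, `estimate`, plus probe-index columns
#'   `first_probe`, `last_probe`.
#' @export
pcf_single <- function(values, positions, params = seg_params()) {
  pcf_core(matrix(values, ncol = 1), positions, params)
}

#' Joint multi-sample PCF with shared breakpoints
#'
#' Exact minimizer of the summed within-segment error over all samples plus
#' `gamma` per additional shared segment; all samples receive identical
#' breakpoints and sample-specific segment means. With a single column this
#' reduces exactly to [pcf_single()].
#'
#' @param values numeric matrix, probes x samples, one chromosome.
#' @param positions probe bp positions.
#' @param params a [seg_params()] object.
#' @return list with `segments` (data frame as in [pcf_single()] without
#'   `estimate`) and `estimates` (matrix, segments x samples).
#' @export
multipcf <- function(values, positions, params = seg_params()) {
  values <- as.matrix(values)
  res <- pcf_core(values, positions, params, all_samples = TRUE)
  res
}

pcf_core <- function(values, positions, params, all_samples = FALSE) {
  stopifnot(nrow(values) == length(positions))
  if (is.unsorted(positions)) stop("probe positions must be sorted ascending")
  n <- nrow(values)
  if (n == 0L) stop("no probes to segment")
  if (n < params$kmin)
    warning("chromosome has fewer than kmin probes; returning one segment")
  starts <- .pcf_dp(values, params$gamma, as.integer(params$kmin))
  ends <- c(starts[-1] - 1L, n)
  b <- probe_bounds(positions)
  seg <- data.frame(start = b$left[starts], end = b$right[ends],
                    n_probes = ends - starts + 1L,
                    first_probe = starts, last_probe = ends)
  est <- vapply(seq_along(starts), function(i)
    colMeans(values[starts[i]:ends[i], , drop = FALSE]),
    numeric(ncol(values)))
  est <- matrix(est, ncol = nrow(seg))  # samples x segments
  if (!all_samples) {
    seg$estimate <- est[1, ]
    seg[, c("start", "end", "n_probes", "estimate",
            "first_probe", "last_probe")]
  } else {
    list(segments = seg, estimates = t(est))
  }
}

#' Segment every sample of an LRR matrix
#'
#' Applies winsorization (optional) and exact PCF per sample and
#' chromosome. Missing probe values are imputed by chromosome-wise
#' nearest-neighbour carry (last observation carried forward, first carried
#' backward) before segmentation, with the imputed count reported. When
#' `joint_by` is supplied (a named vector mapping sample id to patient id),
#' samples of each patient are segmented jointly with shared breakpoints
#' ([multipcf()]).
#'
#' @param x an `lrr_matrix`.
#' @param params a [seg_params()] object.
#' @param winsorize_first clamp outliers before fitting (default TRUE).
#' @param joint_by optional named character vector `sample -> patient` for
#'   patient-wise joint segmentation.
#' @return segment data frame: `sample`, `chrom`, `start`, `end`,
#'   `n_probes`, `estimate`.
#' @export
segment_profiles <- function(x, params = seg_params(), winsorize_first = TRUE,
                             joint_by = NULL) {
  stopifnot(inherits(x, "lrr_matrix"))
  chroms <- unique(x$probes$chrom)
  vals <- x$values
  n_imputed <- 0L
  out <- list()
  groups <- if (is.null(joint_by)) as.list(x$samples) else
    split(x$samples, joint_by[x$samples])
  for (chr in chroms) {
    idx <- which(x$probes$chrom == chr)
    pos <- x$probes$pos[idx]
    for (grp in groups) {
      y <- vals[idx, grp, drop = FALSE]
      if (anyNA(y)) {
        n_imputed <- n_imputed + sum(is.na(y))
        y <- apply(y, 2, impute_carry)
      }
      if (winsorize_first)
        y <- apply(y, 2, winsorize, k = params$winsor_k,
                   tau = params$winsor_tau)
      if (length(grp) == 1L) {
        seg <- suppressWarnings(pcf_single(y[, 1], pos, params))
        out[[length(out) + 1L]] <-
          data.frame(sample = grp, chrom = chr,
                     seg[, c("start", "end", "n_probes", "estimate")],
                     stringsAsFactors = FALSE)
      } else {
        fit <- suppressWarnings(multipcf(y, pos, params))
        for (k in seq_along(grp))
          out[[length(out) + 1L]] <-
            data.frame(sample = grp[k], chrom = chr,
                       fit$segments[, c("start", "end", "n_probes")],
                       estimate = fit$estimates[, k],
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (n_imputed > 0L)
    message(n_imputed, " missing probe value(s) imputed by nearest-neighbour carry")
  seg <- do.call(rbind, out)
  seg <- seg[order(match(seg$sample, x$samples),
                   match(seg$chrom, chroms), seg$start), ]
  rownames(seg) <- NULL
  validate_segments(seg)
  seg
}

impute_carry <- function(v) {
  if (!anyNA(v)) return(v)
  ok <- which(!is.na(v))
  if (length(ok) == 0L) stop("a chromosome has no observed values for a sample")
  idx <- findInterval(seq_along(v), ok)
  idx[idx == 0L] <- 1L
  # carry from nearest observed neighbour (forward, then backward at start)
  v[] <- v[ok[idx]]
  v
}

#' Atomic segments across samples
#'
#' Divides every chromosome into the intervals delimited by the union of
#' all samples' segment breakpoints ("atomic" or longest common segments).
#' Within an atom each sample has a single constant copy number estimate,
#' inherited from its unique parent segment, so atoms make profiles
#' directly comparable as equal-length vectors.
#'
#' @param segments segment data frame covering identical territory per
#'   sample (as from [segment_profiles()]).
#' @param probes optional probe data frame (`chrom`, `pos`) to record probe
#'   counts per atom.
#' @return an `atomic_matrix`: list with `atoms` (data frame `chrom`,
#'   `start`, `end`, `length_bp`, `n_probes`) and `estimates` (matrix,
#'   atoms x samples).
#' @export
atomic_segments <- function(segments, probes = NULL) {
  validate_segments(segments)
  samples <- unique(segments$sample)
  chroms <- unique(segments$chrom)
  atoms <- list(); est <- list()
  for (chr in chroms) {
    sc <- segments[segments$chrom == chr, , drop = FALSE]
    terr <- vapply(samples, function(s) {
      ss <- sc[sc$sample == s, , drop = FALSE]
      if (nrow(ss) == 0L) return(c(NA_real_, NA_real_))
      ss <- ss[order(ss$start), ]
      if (nrow(ss) > 1L && any(ss$start[-1] != ss$end[-nrow(ss)] + 1))
        stop("sample ", s, " has non-contiguous segments on chromosome ", chr)
      c(min(ss$start), max(ss$end))
    }, numeric(2))
    if (anyNA(terr) || length(unique(terr[1, ])) > 1L ||
        length(unique(terr[2, ])) > 1L)
      stop("samples cover inconsistent territory on chromosome ", chr)
    cuts <- sort(unique(sc$start))
    a_start <- cuts
    a_end <- c(cuts[-1] - 1, terr[2, 1])
    np <- if (is.null(probes)) rep(NA_integer_, length(cuts)) else {
      pp <- probes$pos[probes$chrom == chr]
      vapply(seq_along(cuts), function(i)
        sum(pp >= a_start[i] & pp <= a_end[i]), integer(1))
    }
    atoms[[chr]] <- data.frame(chrom = chr, start = a_start, end = a_end,
                               length_bp = a_end - a_start + 1,
                               n_probes = np, stringsAsFactors = FALSE)
    e <- matrix(NA_real_, length(cuts), length(samples),
                dimnames = list(NULL, samples))
    for (s in samples) {
      ss <- sc[sc$sample == s, , drop = FALSE]
      parent <- findInterval(a_start, sort(ss$start))
      e[, s] <- ss$estimate[order(ss$start)][parent]
    }
    est[[chr]] <- e
  }
  out <- list(atoms = do.call(rbind, atoms),
              estimates = do.call(rbind, est), samples = samples)
  rownames(out$atoms) <- NULL
  class(out) <- "atomic_matrix"
  out
}

#' @export
print.atomic_matrix <- function(x, ...) {
  cat("atomic_matrix:", nrow(x$atoms), "atomic segments x",
      length(x$samples), "samples;", sum(x$atoms$length_bp), "bp\n")
  invisible(x)
}

#' Subset an atomic matrix to a set of samples or atoms
#'
#' @param x an `atomic_matrix`.
#' @param samples sample ids to keep (default all).
#' @param atoms logical or integer index of atoms to keep (default all).
#' @return an `atomic_matrix`.
#' @export
subset_atoms <- function(x, samples = x$samples, atoms = NULL) {
  stopifnot(inherits(x, "atomic_matrix"))
  if (is.null(atoms)) atoms <- seq_len(nrow(x$atoms))
  out <- list(atoms = x$atoms[atoms, , drop = FALSE],
              estimates = x$estimates[atoms, samples, drop = FALSE],
              samples = samples)
  rownames(out$atoms) <- NULL
  class(out) <- "atomic_matrix"
  out
}

#' Call copy-number aberrations from estimates
#'
#' Ternary call per estimate: `gain` if the estimate exceeds `+cutoff`,
#' `loss` if below `-cutoff`, `neutral` otherwise (strict inequalities, so
#' an estimate exactly at the cutoff is neutral).
#'
#' @param estimate numeric vector or matrix of copy number estimates.
#' @param cutoff positive aberration threshold (default 0.1).
#' @return character vector/matrix of calls in `{loss, neutral, gain}`.
#' @export
call_aberrations <- function(estimate, cutoff = 0.1) {
  stopifnot(cutoff > 0)
  out <- ifelse(estimate > cutoff, "gain",
                ifelse(estimate < -cutoff, "loss", "neutral"))
  out
}
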