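# Independent oracles and fixture builders used across the suite.
# These deliberately use naive exhaustive algorithms, not the package's
# code paths.

# Exhaustive enumeration of every admissible segmentation (all compositions
# of n into parts >= kmin), returning the minimal value of
#   sum_seg sum_samples SSE + gamma * (#segments - 1)
# Plain recursion, no memoisation: this is a true brute force.
enum_pcf <- function(y, gamma, kmin) {
  y <- as.matrix(y)
  n <- nrow(y)
  seg_sse <- function(i, j) {
    v <- y[i:j, , drop = FALSE]
    sum(sweep(v, 2, colMeans(v))^2)
  }
  if (n < kmin) return(list(cost = seg_sse(1, n), starts = 1L))
  best_cost <- Inf
  best_starts <- NULL
  recurse <- function(start, starts, acc) {
    for (end in (start + kmin - 1):n) {
      if (end < n && n - end < kmin) next
      cost <- acc + seg_sse(start, end)
      if (end == n) {
        tot <- cost + gamma * length(starts)
        if (tot < best_cost - 1e-9) {
          best_cost <<- tot
          best_starts <<- c(starts, start)
        }
      } else {
        recurse(end + 1L, c(starts, start), cost)
      }
    }
  }
  recurse(1L, integer(0), 0)
  list(cost = best_cost, starts = best_starts)
}

# objective value of a fitted segmentation, recomputed from raw data
pcf_objective <- function(y, first, last, gamma) {
  y <- as.matrix(y)
  sse <- sum(vapply(seq_along(first), function(k) {
    v <- y[first[k]:last[k], , drop = FALSE]
    sum(sweep(v, 2, colMeans(v))^2)
  }, numeric(1)))
  sse + gamma * (length(first) - 1)
}

# naive complete-linkage agglomeration; returns sorted merge heights
brute_complete_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# build an atomic_matrix directly from an estimates matrix (atoms x samples)
make_atoms <- function(estimates, length_bp = NULL, chrom = "1") {
  m <- nrow(estimates)
  if (is.null(colnames(estimates)))
    colnames(estimates) <- paste0("s", seq_len(ncol(estimates)))
  if (is.null(length_bp)) length_bp <- rep(100, m)
  start <- cumsum(c(1, length_bp[-m]))
  structure(list(atoms = data.frame(chrom = chrom, start = start,
                                    end = start + length_bp - 1,
                                    length_bp = length_bp,
                                    n_probes = NA_integer_,
                                    stringsAsFactors = FALSE),
                 estimates = estimates, samples = colnames(estimates)),
            class = "atomic_matrix")
}

# random piecewise-constant multi-sample segment set on a shared probe grid
random_profiles <- function(n_samples, n_probes, kmin = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- sort(sample.int(n_probes * 50, n_probes))
  rows <- list()
  for (s in seq_len(n_samples)) {
    nb <- sample(0:3, 1)
    cand <- which(seq_len(n_probes) > kmin & seq_len(n_probes) <= n_probes - kmin + 1)
    starts <- sort(unique(c(1L, if (nb > 0 && length(cand))
      sample(cand, min(nb, length(cand))))))
    ends <- c(starts[-1] - 1L, n_probes)
    b <- methet:::probe_bounds(pos)
    rows[[s]] <- data.frame(sample = paste0("s", s), chrom = "1",
                            start = b$left[starts], end = b$right[ends],
                            n_probes = ends - starts + 1L,
                            estimate = round(stats::rnorm(length(starts)), 3),
                            stringsAsFactors = FALSE)
  }
  list(segments = do.call(rbind, rows), pos = pos)
}

# two-patient toy clinical table
toy_clinical <- function() {
  as_cohort_table(data.frame(
    patient = c("P1", "P1", "P2", "P2"),
    sample = c("a", "b", "c", "d"),
    resection = c(1L, 1L, 1L, 2L),
    synchronous = c(1L, 1L, 0L, 0L),
    chemo = c(0L, 0L, 1L, 1L),
    tp53 = "wildtype", age = 60L, sex = "F",
    ccf = c(0.5, 0.7, 0.6, NA),
    pfs_time = c(10, 10, 20, 20), pfs_event = c(1L, 1L, 0L, 0L),
    os_time = c(15, 15, 30, 30), os_event = c(1L, 1L, 0L, 0L),
    stringsAsFactors = FALSE))
}
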