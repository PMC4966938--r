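#' Complete-linkage clustering of deposits
#'
#' Deterministic complete-linkage agglomeration on pairwise Euclidean
#' distances between samples' atomic copy number estimate vectors, after
#' the cross-sample variance filter. Exploratory view of inter-metastatic
#' heterogeneity: deposits of a genetically homogeneous patient merge at
#' low height, heterogeneous patients split across clusters.
#'
#' @param x an `atomic_matrix` with >= 2 samples.
#' @param variance_cutoff variance filter cutoff (default 0.03; `"none"`
#'   disables).
#' @return a `cluster_tree`: list with the `hclust` fit, sample `labels`,
#'   and `nodes` (one entry per internal node: sorted member labels and
#'   merge `height`).
#' @export
cluster_samples <- function(x, variance_cutoff = 0.03) {
  stopifnot(inherits(x, "atomic_matrix"))
  if (length(x$samples) < 2L) stop("clustering needs >= 2 samples")
  xf <- variance_filter(x, variance_cutoff)
  hc <- stats::hclust(stats::dist(t(xf$estimates)), method = "complete")
  tree <- list(hclust = hc, labels = hc$labels,
               nodes = hclust_nodes(hc), matrix = xf)
  class(tree) <- "cluster_tree"
  tree
}

# member label sets per internal node of an hclust fit
hclust_nodes <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) hc$labels[-j] else members[[j]]$members
    members[[i]] <- list(members = sort(c(pick(hc$merge[i, 1]),
                                          pick(hc$merge[i, 2]))),
                         height = hc$height[i])
  }
  members
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree:", length(x$labels), "samples,",
      length(x$nodes), "internal nodes (complete linkage, Euclidean)\n")
  if (!is.null(x$support))
    cat("  multiscale bootstrap support attached (n_boot =",
        x$support$n_boot, ")\n")
  invisible(x)
}

#' Multiscale bootstrap support for clusters (AU and BP values)
#'
#' Resamples atomic segments (the clustering features) with replacement at
#' a grid of resampling scales r, re-clusters each replicate, and counts
#' the bootstrap probability BP_r that each original node's member set
#' reappears. The approximately unbiased (AU) probability corrects BP for
#' the bias of simple bootstrap support by fitting
#' \deqn{\Phi^{-1}(1 - BP_r) = v\sqrt{r} + c/\sqrt{r}}
#' across scales by weighted least squares and reporting
#' \eqn{AU = 1 - \Phi(v - c)}. BP is reported at scale r = 1. Only scales
#' with BP strictly inside (0.001, 0.999) inform the fit (BP at the
#' boundary carries no probit information); when fewer than three scales
#' are informative the fit is degenerate and AU falls back to 1 if the
#' mean BP is at least 0.5 and 0 otherwise, as in the published
#' multiscale-bootstrap procedure. BP values are additionally clipped to
#' 1/(2 n_boot) from the boundary before the probit transform (continuity
#' correction). A node never recovered at any scale gets AU = 0 and is
#' flagged.
#'
#' @param x an `atomic_matrix`.
#' @param variance_cutoff variance filter cutoff applied before clustering.
#' @param scales resampling scale grid (default 0.5 to 1.4 by 0.1).
#' @param n_boot bootstrap replicates per scale (default 1000).
#' @param seed integer seed; fixed seed gives bit-identical supports.
#' @return a `cluster_tree` whose `support` element holds per-node `au`,
#'   `bp` (at r = 1), `never_recovered` flags and the per-scale BP matrix.
#' @export
multiscale_bootstrap <- function(x, variance_cutoff = 0.03,
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 n_boot = 1000, seed = 1) {
  tree <- cluster_samples(x, variance_cutoff)
  xf <- tree$matrix
  e <- xf$estimates
  m <- nrow(e)
  sig0 <- vapply(tree$nodes, function(nd)
    paste(nd$members, collapse = "\r"), character(1))
  n_nodes <- length(sig0)
  set.seed(seed)
  counts <- matrix(0L, n_nodes, length(scales))
  for (si in seq_along(scales)) {
    m_r <- max(1L, round(m * scales[si]))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(m, m_r, replace = TRUE)
      hb <- stats::hclust(stats::dist(t(e[idx, , drop = FALSE])),
                          method = "complete")
      sigs <- vapply(hclust_nodes(hb), function(nd)
        paste(nd$members, collapse = "\r"), character(1))
      counts[, si] <- counts[, si] + (sig0 %in% sigs)
    }
  }
  bp <- counts / n_boot
  r_actual <- pmax(1L, round(m * scales)) / m
  eps <- 1 / (2 * n_boot)
  au <- numeric(n_nodes)
  never <- rowSums(counts) == 0L
  for (k in seq_len(n_nodes)) {
    if (never[k]) { au[k] <- 0; next }
    use <- bp[k, ] > 0.001 & bp[k, ] < 0.999
    if (sum(use) < 3L) {  # degenerate: BP pinned at a boundary
      au[k] <- if (mean(bp[k, ]) >= 0.5) 1 else 0
      next
    }
    bpk <- pmin(pmax(bp[k, use], eps), 1 - eps)
    z <- stats::qnorm(1 - bpk)
    w <- n_boot * stats::dnorm(z)^2 / (bpk * (1 - bpk))
    X <- cbind(sqrt(r_actual[use]), 1 / sqrt(r_actual[use]))
    fit <- stats::lm.wfit(X, z, w)
    v <- fit$coefficients[1]; cc <- fit$coefficients[2]
    au[k] <- 1 - stats::pnorm(v - cc)
  }
  bp1 <- bp[, which.min(abs(r_actual - 1))]
  tree$support <- list(au = au, bp = bp1, bp_by_scale = bp,
                       scales = r_actual, never_recovered = never,
                       n_boot = n_boot, seed = seed)
  tree
}

#' Patient-wise cluster purity
#'
#' A patient is monophyletic if some node of the tree contains exactly the
#' patient's samples (equivalently, all its deposits merge before any
#' unrelated deposit joins); otherwise the patient's deposits are split
#' across clusters. Single-deposit patients are not assessable.
#'
#' @param tree a `cluster_tree`.
#' @param cohort a `cohort_table`.
#' @param resection resection index (default 1).
#' @return data frame `patient`, `n_samples`, `status` in
#'   `{monophyletic, split, not assessable}`.
#' @export
patient_cluster_purity <- function(tree, cohort, resection = 1) {
  stopifnot(inherits(tree, "cluster_tree"))
  node_sigs <- vapply(tree$nodes, function(nd)
    paste(nd$members, collapse = "\r"), character(1))
  patients <- unique(cohort$patient)
  rows <- lapply(patients, function(p) {
    smp <- sort(intersect(patient_samples(cohort, p, resection), tree$labels))
    status <- if (length(smp) < 2L) "not assessable"
    else if (paste(smp, collapse = "\r") %in% node_sigs) "monophyletic"
    else "split"
    data.frame(patient = p, n_samples = length(smp), status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a cluster tree in Newick format
#'
#' Internal node labels carry the bootstrap support as `au|bp` (per cent,
#' rounded to one decimal) when support has been computed.
#'
#' @param tree a `cluster_tree`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
cluster_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  hc <- tree$hclust
  lab <- function(i) {
    if (is.null(tree$support)) return("")
    sprintf("%.1f|%.1f", 100 * tree$support$au[i], 100 * tree$support$bp[i])
  }
  build <- function(i, parent_h) {
    if (i < 0)
      return(sprintf("%s:%s", hc$labels[-i], fmt_num(parent_h)))
    h <- hc$height[i]
    sprintf("(%s,%s)%s:%s",
            build(hc$merge[i, 1], h), build(hc$merge[i, 2], h),
            lab(i), fmt_num(parent_h - h))
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  nwk <- sprintf("(%s,%s)%s;",
                 build(hc$merge[root, 1], h), build(hc$merge[root, 2], h),
                 lab(root))
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}
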