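#' Administrative censoring at a follow-up horizon
#'
#' Truncates follow-up at `horizon` months: times beyond the horizon are
#' censored there, so all analyses address the fixed-horizon endpoints
#' (3-year progression-free and overall survival by default).
#'
#' @param time event/censoring time in months (>= 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @param horizon months (default 36).
#' @return data frame `time`, `event` after censoring.
#' @export
censor_at_horizon <- function(time, event, horizon = 36) {
  if (any(time < 0, na.rm = TRUE)) stop("negative survival time")
  data.frame(time = pmin(time, horizon),
             event = as.integer(event == 1 & time <= horizon))
}

#' Kaplan-Meier survival probability at the horizon, per group
#'
#' Product-limit estimate of survival at `horizon` months within each
#' group, after administrative censoring.
#'
#' @param time,event survival endpoint per subject.
#' @param group group label per subject.
#' @param horizon months (default 36).
#' @return data frame `group`, `n`, `rate` (per cent surviving at the
#'   horizon; `NA` when the estimate is undefined there).
#' @export
three_year_rate <- function(time, event, group, horizon = 36) {
  d <- censor_at_horizon(time, event, horizon)
  d$group <- group
  out <- lapply(split(d, d$group), function(g) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = g)
    s <- summary(fit, times = horizon, extend = TRUE)
    data.frame(group = g$group[1], n = nrow(g),
               rate = 100 * s$surv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Log-rank test, including the test of linear trend
#'
#' Ordinary log-rank for two groups; for ordered strata with equally
#' spaced scores 0, 1, 2, ... the 1-df linear-trend statistic
#' \eqn{(c'(O-E))^2 / (c'Vc)} built from the stratum-wise observed and
#' expected event counts and their covariance. With two strata the trend
#' test reduces exactly to the ordinary log-rank test.
#'
#' @param time,event survival endpoint per subject.
#' @param strata ordered factor (or values coercible to one).
#' @param horizon optional administrative censoring horizon in months.
#' @return list with `chisq`, `df` (= 1), `p`, and the per-stratum
#'   observed/expected table.
#' @export
logrank_trend <- function(time, event, strata, horizon = NULL) {
  if (!is.null(horizon)) {
    d <- censor_at_horizon(time, event, horizon)
    time <- d$time; event <- d$event
  }
  strata <- as.factor(strata)
  if (nlevels(droplevels(strata)) < 2L) stop("need >= 2 non-empty strata")
  if (any(table(strata) == 0L)) stop("empty stratum")
  sd <- survival::survdiff(survival::Surv(time, event) ~ strata)
  k <- length(sd$obs)
  sc <- seq_len(k) - 1
  num <- sum(sc * (sd$obs - sd$exp))
  den <- as.numeric(t(sc) %*% sd$var %*% sc)
  chisq <- num^2 / den
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       table = data.frame(stratum = levels(strata), n = as.vector(sd$n),
                          observed = sd$obs, expected = sd$exp))
}

#' Cox proportional hazards fit with Wald tests
#'
#' Partial-likelihood estimates (Efron tie handling) with hazard ratios,
#' 95% confidence intervals and Wald P-values per covariate, after
#' optional administrative censoring at the horizon. The proportional
#' hazards assumption is checked with the scaled Schoenfeld residual test.
#' A rank-deficient design (e.g. duplicated covariate columns) is an
#' error; non-convergence is flagged rather than silently reported.
#'
#' @param time,event survival endpoint per subject.
#' @param covariates data frame of covariates (numeric or factor).
#' @param horizon optional censoring horizon in months.
#' @return data frame with one row per model coefficient: `term`, `hr`,
#'   `lo95`, `hi95`, `p`, plus attributes `ph_global_p` (proportional
#'   hazards check) and `converged`.
#' @export
cox_fit <- function(time, event, covariates, horizon = NULL) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(time))
  if (!is.null(horizon)) {
    d <- censor_at_horizon(time, event, horizon)
    time <- d$time; event <- d$event
  }
  if (sum(event) < 1L) stop("no events")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  out <- data.frame(term = rownames(sm$coefficients),
                    hr = sm$conf.int[, "exp(coef)"],
                    lo95 = sm$conf.int[, "lower .95"],
                    hi95 = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  ph <- tryCatch(survival::cox.zph(fit)$table, error = function(e) NULL)
  attr(out, "ph_global_p") <- if (is.null(ph)) NA_real_ else
    ph["GLOBAL", "p"]
  attr(out, "converged") <- converged
  out
}

#' Univariable screening followed by one-step multivariable Cox model
#'
#' Fits each covariate alone, then enters every covariate with a
#' univariable Wald P below `enter_p` (default 0.1) into a single
#' multivariable model in one step.
#'
#' @param time,event survival endpoint per subject.
#' @param covariates data frame of candidate covariates.
#' @param enter_p univariable P-value threshold for multivariable entry.
#' @param horizon optional censoring horizon in months.
#' @return list with `univariable` (stacked per-covariate results),
#'   `multivariable` (or `NULL` if < 2 covariates qualify), and `entered`.
#' @export
cox_screen <- function(time, event, covariates, enter_p = 0.1,
                       horizon = NULL) {
  uni <- do.call(rbind, lapply(names(covariates), function(v) {
    r <- tryCatch(cox_fit(time, event, covariates[, v, drop = FALSE],
                          horizon),
                  error = function(e)
                    data.frame(term = v, hr = NA_real_, lo95 = NA_real_,
                               hi95 = NA_real_, p = NA_real_,
                               stringsAsFactors = FALSE))
    r$covariate <- v
    r
  }))
  qual <- unique(uni$covariate[!is.na(uni$p) & uni$p < enter_p])
  multi <- if (length(qual) >= 2L)
    cox_fit(time, event, covariates[, qual, drop = FALSE], horizon)
  else NULL
  list(univariable = uni, multivariable = multi, entered = qual)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' a two-sided P-value. Degenerate inputs (zero variance in both groups)
#' return P = 1 when the means are equal, by convention, and P = 0
#' otherwise.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Segment-wise group comparison with FDR control
#'
#' Welch t-test of the copy number estimate of every atomic segment
#' between two sample groups, with Benjamini-Hochberg adjusted q-values
#' and the atoms ranked by P. Atoms constant in both groups get q = 1.
#' The Welch statistics are computed vectorised over atoms (validated
#' against `t.test` in the test suite).
#'
#' @param x an `atomic_matrix`.
#' @param groups factor of length `length(x$samples)` with two levels.
#' @return data frame of atoms with `t`, `df`, `p`, `q`, sorted by `p`.
#' @export
segmentwise_group_test <- function(x, groups) {
  stopifnot(inherits(x, "atomic_matrix"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  if (length(i1) < 2L || length(i2) < 2L) stop("each group needs >= 2 samples")
  e1 <- x$estimates[, i1, drop = FALSE]
  e2 <- x$estimates[, i2, drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(e1); m2 <- rowMeans(e2)
  v1 <- rowSums((e1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((e2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  const <- se2 == 0
  p[const & (m1 == m2)] <- 1
  p[const & (m1 != m2)] <- 0
  t[const] <- 0
  out <- cbind(x$atoms, t = t, df = df, p = p,
               q = stats::p.adjust(p, method = "BH"))
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Median split of a biomarker score
#'
#' Two-group assignment at the cohort median; a patient exactly at the
#' median goes to the HIGH group, so with an odd number of patients the
#' split is (n-1)/2 low and (n+1)/2 high.
#'
#' @param score numeric vector (NAs excluded from the median and labelled
#'   `NA`).
#' @return factor with ordered levels `low` < `high`.
#' @export
median_split <- function(score) {
  med <- stats::median(score, na.rm = TRUE)
  factor(ifelse(score < med, "low", "high"), levels = c("low", "high"),
         ordered = TRUE)
}

#' Combined heterogeneity-by-complexity stratification
#'
#' Three ordered strata: `both_low` (heterogeneity below the cohort median
#' AND genomic complexity below the threshold), `one_low` (exactly one of
#' the two), and `neither_low`. Patients missing either score are excluded
#' (returned as `NA`).
#'
#' @param het per-patient heterogeneity score.
#' @param cx per-patient genomic complexity (per cent).
#' @param cx_threshold complexity threshold in per cent (default 25).
#' @return ordered factor `both_low < one_low < neither_low`.
#' @export
combined_strata <- function(het, cx, cx_threshold = 25) {
  het_low <- het < stats::median(het, na.rm = TRUE)
  cx_low <- cx < cx_threshold
  n_low <- het_low + cx_low
  out <- factor(c("neither_low", "one_low", "both_low")[n_low + 1L],
                levels = c("both_low", "one_low", "neither_low"),
                ordered = TRUE)
  out[is.na(het) | is.na(cx)] <- NA
  out
}
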