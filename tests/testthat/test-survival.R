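test_that("horizon censoring and KM rates follow the product limit", {
  # no events by 36 months -> 100%
  r <- three_year_rate(c(40, 50, 60, 70), c(1, 1, 1, 1), rep("g", 4))
  expect_equal(r$rate, 100)
  # all events before 36 -> 0%
  r2 <- three_year_rate(c(10, 20), c(1, 1), rep("g", 2))
  expect_equal(r2$rate, 0)
  # one event at 12 among 4 subjects censored at 36 -> 75%
  r3 <- three_year_rate(c(12, 36, 36, 36), c(1, 0, 0, 0), rep("g", 4))
  expect_equal(r3$rate, 75)
  expect_error(three_year_rate(c(-1, 2), c(1, 1), c("g", "g")), "negative")

  cc <- censor_at_horizon(c(10, 40), c(1, 1), 36)
  expect_equal(cc$time, c(10, 36))
  expect_equal(cc$event, c(1L, 0L))
})

test_that("log-rank trend reduces to the two-group log-rank", {
  set.seed(41)
  tm <- rexp(60, rep(c(0.05, 0.15), each = 30))
  ev <- rep(1L, 60)
  g <- rep(c("low", "high"), each = 30)
  lt <- logrank_trend(tm, ev, factor(g, levels = c("low", "high")))
  sd2 <- survival::survdiff(survival::Surv(tm, ev) ~ g)
  expect_equal(lt$chisq, sd2$chisq, tolerance = 1e-9)

  # identical survival in all strata: statistic near 0, p near 1
  set.seed(42)
  tm0 <- rexp(150, 0.1)
  s3 <- rep(c("a", "b", "c"), each = 50)
  lt0 <- logrank_trend(tm0, rep(1L, 150), factor(s3))
  expect_lt(lt0$chisq, 4)
  expect_gt(lt0$p, 0.01)
  expect_error(logrank_trend(tm0, rep(1L, 150),
                             factor(s3, levels = c("a", "b", "c", "d"))),
               "empty stratum")
})

test_that("ordered hazards are detected by the trend test", {
  set.seed(43)
  detected <- 0L
  for (rep in 1:20) {
    haz <- rep(c(1, 2, 4) * 0.02, each = 100)
    tm <- rexp(300, haz)
    strata <- factor(rep(c("s0", "s1", "s2"), each = 100))
    p <- logrank_trend(tm, rep(1L, 300), strata)$p
    detected <- detected + (p < 0.05)
  }
  expect_gte(detected, 18L)  # >= 90% power at this effect size
})

test_that("Cox fits recover hazard ratios and flag degenerate designs", {
  set.seed(44)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.05 * exp(log(0.4) * x))
  cens <- runif(n, 0, 80)
  fit <- cox_fit(pmin(tm, cens), as.integer(tm <= cens), data.frame(x = x))
  expect_equal(nrow(fit), 1L)
  expect_gt(fit$hr, 0.2)
  expect_lt(fit$hr, 0.8)
  expect_true(fit$lo95 < fit$hr && fit$hr < fit$hi95)
  expect_lt(fit$p, 0.05)
  expect_true(is.finite(attr(fit, "ph_global_p")))

  expect_error(cox_fit(pmin(tm, cens), as.integer(tm <= cens),
                       data.frame(x = x, x2 = x)), "rank-deficient")
  expect_error(cox_fit(tm, rep(0L, n), data.frame(x = x)), "no events")
})

test_that("univariable screening feeds the one-step multivariable model", {
  set.seed(45)
  n <- 150
  strong <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  tm <- rexp(n, 0.05 * exp(1 * strong))
  res <- cox_screen(tm, rep(1L, n),
                    data.frame(strong = strong, noise = noise),
                    enter_p = 0.1)
  expect_true("strong" %in% res$entered)
  expect_equal(nrow(res$univariable), 2L)
  if (!is.null(res$multivariable))
    expect_true(all(c("strong", "noise") %in% res$multivariable$term))
})

test_that("Welch t-test handles degenerate and standard inputs", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- welch_t(c(0, 0, 0, 0), c(1, 1, 1, 1.0001))
  expect_lt(r2$p, 0.001)
  # swapping groups flips the sign, not the p-value
  set.seed(46)
  a <- rnorm(10); b <- rnorm(12, 1)
  r3 <- welch_t(a, b); r4 <- welch_t(b, a)
  expect_equal(r3$t, -r4$t)
  expect_equal(r3$p, r4$p)
  # agreement with the reference implementation
  ht <- t.test(a, b, var.equal = FALSE)
  expect_equal(r3$t, unname(ht$statistic))
  expect_equal(r3$p, ht$p.value)
  # both groups constant at the same value
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
})

test_that("segment-wise tests match t.test and rank injected signal first", {
  set.seed(47)
  e <- matrix(rnorm(50 * 12, 0, 0.1), 50,
              dimnames = list(NULL, paste0("s", 1:12)))
  groups <- rep(c("g1", "g2"), each = 6)
  e[7, groups == "g2"] <- e[7, groups == "g2"] + 1.0
  at <- make_atoms(e)
  res <- segmentwise_group_test(at, groups)
  expect_equal(res$start[1], at$atoms$start[7])  # injected atom ranks first
  expect_lt(res$q[1], 0.05)
  # vectorised Welch equals t.test atom by atom
  for (i in c(1, 7, 20)) {
    ht <- t.test(e[i, groups == "g1"], e[i, groups == "g2"],
                 var.equal = FALSE)
    row <- res[res$start == at$atoms$start[i], ]
    expect_equal(row$p, ht$p.value, tolerance = 1e-12)
  }
  # BH q-values are non-decreasing in p order
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-15))
  # constant atoms in both groups get q = 1
  e2 <- e
  e2[3, ] <- 0.2
  res2 <- segmentwise_group_test(make_atoms(e2), groups)
  expect_equal(res2$q[res2$start == at$atoms$start[3]], 1)
})

test_that("median split and combined strata follow the threshold rules", {
  # odd cohort: patient exactly at the median goes to the high group
  g <- median_split(c(1, 2, 3, 4, 5))
  expect_equal(as.character(g), c("low", "low", "high", "high", "high"))
  expect_equal(sum(g == "low"), 2L)

  het <- c(1, 5, 5, 1)      # median 3
  cx <- c(10, 10, 60, 60)
  st <- combined_strata(het, cx, cx_threshold = 25)
  expect_equal(as.character(st),
               c("both_low", "one_low", "neither_low", "one_low"))
  st2 <- combined_strata(c(1, 5, NA), c(10, 10, 10))
  expect_true(is.na(st2[3]))
})
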