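test_that("winsorization clamps outliers and is idempotent", {
  expect_equal(winsorize(rep(1.5, 40)), rep(1.5, 40))
  set.seed(11)
  x <- rnorm(200)
  x[100] <- 10
  w <- winsorize(x)
  expect_lt(w[100], 10)
  expect_gt(w[100], 0)
  expect_equal(length(w), length(x))
  # all outputs lie within their own local clamp bounds: re-application of
  # the same clamp cannot move anything further
  expect_equal(winsorize(w), w)
})

test_that("pcf_single minimizes the penalized least-squares objective", {
  # a clean step: splitting costs gamma = 0.5 but removes SSE 2.5
  y <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  fit <- pcf_single(y, seq_along(y) * 10, seg_params(gamma = 0.5, kmin = 5))
  expect_equal(nrow(fit), 2L)
  expect_equal(fit$estimate, c(0, 1))
  expect_equal(fit$n_probes, c(5L, 5L))

  # constant input: one segment at the constant, for any positive gamma
  fit2 <- pcf_single(rep(0.7, 30), 1:30, seg_params(gamma = 0.01, kmin = 1))
  expect_equal(nrow(fit2), 1L)
  expect_equal(fit2$estimate, 0.7)

  # huge gamma: one segment at the global mean
  set.seed(3)
  y3 <- rnorm(50)
  fit3 <- pcf_single(y3, 1:50, seg_params(gamma = 1e6, kmin = 5))
  expect_equal(nrow(fit3), 1L)
  expect_equal(fit3$estimate, mean(y3))

  # fewer than kmin probes: single segment with a warning
  expect_warning(fit4 <- pcf_single(c(1, 2), 1:2, seg_params(kmin = 5)),
                 "fewer than kmin")
  expect_equal(nrow(fit4), 1L)
})

test_that("breakpoint count is non-increasing in gamma", {
  set.seed(21)
  for (rep in 1:5) {
    y <- rnorm(60) + rep(sample(c(-1, 0, 1), 4, replace = TRUE), each = 15)
    nseg <- vapply(c(0.5, 2, 8, 32, 128), function(g)
      nrow(pcf_single(y, 1:60, seg_params(gamma = g, kmin = 3))), numeric(1))
    expect_true(all(diff(nseg) <= 0))
  }
})

test_that("multipcf shares breakpoints across samples and reduces to pcf_single", {
  pos <- 1:12 * 100
  a <- c(rep(0, 6), rep(1, 6))
  b <- c(rep(0.5, 6), rep(-0.5, 6))
  prm <- seg_params(gamma = 0.3, kmin = 3)

  # single sample: identical to pcf_single
  f1 <- pcf_single(a, pos, prm)
  fm <- multipcf(matrix(a, ncol = 1), pos, prm)
  expect_equal(fm$segments$start, f1$start)
  expect_equal(as.vector(fm$estimates), f1$estimate)

  # same step position: one shared breakpoint
  f2 <- multipcf(cbind(a, b), pos, prm)
  expect_equal(nrow(f2$segments), 2L)
  expect_equal(f2$estimates[, 1], c(0, 1))
  expect_equal(f2$estimates[, 2], c(0.5, -0.5))

  # steps at different probes, small gamma: both breakpoints in the shared set
  c1 <- c(rep(0, 4), rep(1, 8))
  c2 <- c(rep(0, 8), rep(1, 4))
  f3 <- multipcf(cbind(c1, c2), pos, seg_params(gamma = 0.1, kmin = 3))
  expect_equal(f3$segments$first_probe, c(1L, 5L, 9L))

  # duplicated identical samples: same breakpoints as one copy
  f4 <- multipcf(cbind(a, a, a), pos, prm)
  expect_equal(f4$segments$start, f1$start)
})

test_that("joint fit matches exhaustive enumeration on small instances", {
  set.seed(31)
  for (rep in 1:10) {
    y <- matrix(rnorm(10 * 2), 10, 2)
    prm <- seg_params(gamma = sample(c(0.5, 2, 10), 1), kmin = sample(2:3, 1))
    fit <- multipcf(y, 1:10, prm)
    got <- pcf_objective(y, fit$segments$first_probe, fit$segments$last_probe,
                         prm$gamma)
    want <- enum_pcf(y, prm$gamma, prm$kmin)$cost
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("atomic segments are the union-of-breakpoints partition", {
  b <- methet:::probe_bounds(1:10 * 100)
  seg <- function(s, starts, ends, est)
    data.frame(sample = s, chrom = "1", start = b$left[starts],
               end = b$right[ends], n_probes = ends - starts + 1L,
               estimate = est, stringsAsFactors = FALSE)
  # A: one segment; B: split at probe 6 -> 2 atoms, A's estimate repeated
  segs <- rbind(seg("A", 1, 10, 0.2),
                seg("B", c(1, 6), c(5, 10), c(0, 1)))
  at <- atomic_segments(segs)
  expect_equal(nrow(at$atoms), 2L)
  expect_equal(at$estimates[, "A"], c(0.2, 0.2))
  expect_equal(at$estimates[, "B"], c(0, 1))
  expect_equal(sum(at$atoms$length_bp), 1000 - 100 + 1)

  # identical segmentations: atoms = original segments
  segs2 <- rbind(seg("A", c(1, 6), c(5, 10), c(0, 1)),
                 seg("B", c(1, 6), c(5, 10), c(2, 3)))
  at2 <- atomic_segments(segs2)
  expect_equal(nrow(at2$atoms), 2L)

  # breakpoint sets {p1}, {p2}, {p1, p2} -> 3 atoms
  segs3 <- rbind(seg("A", c(1, 4), c(3, 10), c(0, 1)),
                 seg("B", c(1, 8), c(7, 10), c(2, 3)),
                 seg("C", c(1, 4, 8), c(3, 7, 10), c(4, 5, 6)))
  at3 <- atomic_segments(segs3)
  expect_equal(nrow(at3$atoms), 3L)
  expect_equal(at3$estimates[, "A"], c(0, 1, 1))
  expect_equal(at3$estimates[, "B"], c(2, 2, 3))
  expect_equal(at3$estimates[, "C"], c(4, 5, 6))

  # mismatched territory is an error
  segs4 <- rbind(seg("A", 1, 10, 0), seg("B", 1, 8, 0))
  expect_error(atomic_segments(segs4), "territory")
})

test_that("aberration calls use strict inequalities at the cutoff", {
  expect_identical(call_aberrations(c(0.10, 0.100001, -0.3, 0), cutoff = 0.1),
                   c("neutral", "gain", "loss", "neutral"))
  # monotonically fewer aberrant calls as the cutoff grows
  set.seed(5)
  est <- rnorm(300, 0, 0.15)
  n_ab <- vapply(c(0.05, 0.1, 0.2), function(ct)
    sum(call_aberrations(est, ct) != "neutral"), numeric(1))
  expect_true(all(diff(n_ab) <= 0))
})

test_that("segment_profiles imputes missing values and segments per sample", {
  g <- genome_build("1", 2000)
  pos <- 1:20 * 100
  set.seed(8)
  vals <- matrix(c(rep(0, 10), rep(1, 10), rep(0.5, 20)) +
                   rnorm(40, 0, 0.01), ncol = 2,
                 dimnames = list(NULL, c("s1", "s2")))
  vals[3, 1] <- NA
  probes <- data.frame(marker = paste0("m", 1:20), chrom = "1", pos = pos,
                       class = "SNP", stringsAsFactors = FALSE)
  x <- lrr_matrix(probes, vals, g)
  expect_message(seg <- segment_profiles(x, seg_params(gamma = 1, kmin = 5)),
                 "1 missing probe value")
  expect_equal(sum(seg$sample == "s1"), 2L)
  expect_equal(sum(seg$sample == "s2"), 1L)
  # joint segmentation gives both samples identical breakpoints
  seg_j <- suppressMessages(segment_profiles(
    x, seg_params(gamma = 1, kmin = 5),
    joint_by = c(s1 = "P1", s2 = "P1")))
  expect_identical(seg_j$start[seg_j$sample == "s1"],
                   seg_j$start[seg_j$sample == "s2"])
})
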