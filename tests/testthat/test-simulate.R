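small_cfg <- function(...) {
  args <- list(n_patients = 4, genome_scale = 0.1, probe_spacing = 1e5,
               n_second_patients = 0, seed = 101)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}

test_that("degenerate event rates give diploid or clonal-only cohorts", {
  cfg0 <- small_cfg(lambda_anc = 0, lambda_div = 0, lambda_cnloh = 0)
  p <- simulate_patient(cfg0, 1)
  for (d in p$deposits) {
    expect_true(all(d$nA == 1L & d$nB == 1L))
  }
  expect_true(is.na(p$true_divergence) || p$true_divergence == 0)

  # clonal events only: deposits identical to the ancestor, divergence 0
  cfg1 <- small_cfg(lambda_anc = 10, lambda_div = 0, lambda_cnloh = 0)
  for (i in 1:3) {
    p1 <- simulate_patient(cfg1, i)
    if (length(p1$deposits) >= 2) {
      expect_equal(p1$true_divergence, 0)
      expect_identical(p1$deposits[[1]], p1$ancestor)
    }
    expect_gt(mean(p1$aberrant_fraction), 0)
  }
})

test_that("true divergence grows with the private-event rate", {
  div_at <- function(lam) {
    cfg <- sim_config(n_patients = 30, genome_scale = 0.1,
                      probe_spacing = 1e5, n_second_patients = 0,
                      lambda_div = lam, deposit_probs = c(0, 1),
                      seed = 202)
    mean(vapply(seq_len(cfg$n_patients), function(i)
      simulate_patient(cfg, i)$true_divergence, numeric(1)))
  }
  expect_gt(div_at(5), div_at(1))
})

test_that("rendered log ratios follow the purity mixture formula", {
  profile <- data.frame(chrom = "1", start = c(1, 1001, 2001),
                        end = c(1000, 2000, 3000),
                        nA = c(1L, 2L, 0L), nB = c(1L, 1L, 0L),
                        stringsAsFactors = FALSE)
  probes <- data.frame(chrom = "1", pos = c(500L, 1500L, 2500L))
  expect_equal(render_lrr(profile, 1, 0, probes),
               c(0, log2(3 / 2), -4))
  expect_equal(render_lrr(profile, 0.5, 0, probes),
               c(0, log2(2.5 / 2), log2(0.5)))
  # diploid loci have mean 0 under noise
  set.seed(55)
  many <- data.frame(chrom = "1", pos = seq(10L, 990L, 10L))
  lrr <- render_lrr(profile[1, ], 0.7, 0.1, many)
  expect_lt(abs(mean(lrr)), 0.05)
})

test_that("survival generation respects the hazard and censoring settings", {
  het <- 1:200
  s <- simulate_survival(het, median_months = 12, hr = 0.4,
                         censoring = 0.3, seed = 7)
  expect_equal(sort(unique(s$group)), c("high", "low"))
  # censored fraction near the 30% target
  expect_lt(abs(mean(1 - s$event) - 0.3), 0.1)
  # no censoring / full censoring
  s0 <- simulate_survival(het, 12, 0.4, 0, seed = 7)
  expect_true(all(s0$event == 1L))
  s1 <- simulate_survival(het, 12, 0.4, 1, seed = 7)
  expect_true(all(s1$event == 0L))
  expect_equal(three_year_rate(s1$time, s1$event, s1$group)$rate, c(100, 100))
  # under the null the groups are exchangeable
  sn <- simulate_survival(het, 12, 1, 0, seed = 8)
  p <- logrank_trend(sn$time, sn$event,
                     factor(sn$group, levels = c("low", "high")))$p
  expect_gt(p, 0.001)
})

test_that("cohort emission is deterministic and consistent with its truth", {
  cfg <- small_cfg()
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  co <- emit_cohort(cfg, d1)
  emit_cohort(cfg, d2)
  for (f in c("lrr.tsv", "allele_truth.tsv", "clinical.csv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # files are readable by the package's own readers
  lrr <- read_lrr_table(file.path(d1, "lrr.tsv"), cfg$genome)
  expect_equal(length(lrr$samples), nrow(co$clinical))
  ap <- read_allele_profiles(file.path(d1, "allele_truth.tsv"))
  clin <- read_clinical(file.path(d1, "clinical.csv"))
  expect_equal(sort(unique(clin$patient)),
               sort(vapply(co$patients, `[[`, "", "patient")))

  # recorded cnLOH fractions match cnloh_fraction() on the truth profiles
  for (p in co$patients) {
    sid <- paste0(p$patient, "_M1")
    expect_equal(cnloh_fraction(ap, sid) / 100, p$cnloh_fraction[1],
                 tolerance = 1e-12)
  }
})

test_that("patient streams are independent of cohort size", {
  cfg_small <- small_cfg()
  cfg_big <- sim_config(n_patients = 9, genome_scale = 0.1,
                        probe_spacing = 1e5, n_second_patients = 0,
                        seed = 101)
  p_small <- simulate_patient(cfg_small, 3)
  p_big <- simulate_patient(cfg_big, 3)
  expect_identical(p_small$deposits, p_big$deposits)
  expect_identical(p_small$purity, p_big$purity)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(seed = 1, purity_range = c(0, 0.9)))
  expect_error(sim_config(seed = 1, censoring = 1.5))
  expect_error(sim_config())
  cfg <- small_cfg(probe_spacing = 1e12)
  expect_error(simulate_cohort(cfg), "no probes")
})

test_that("measured complexity recovers the simulated aberrant fraction", {
  # scaled miniature of the full-density regime: events span >= kmin
  # markers; realistic probe noise and purity dilution
  for (pr in list(c(1, 1), c(0.4, 0.95))) {
    cfg <- small_cfg(n_patients = 6, purity_range = pr, noise_sd = 0.15,
                     focal_min_bp = 1e7, seed = 606)
    co <- simulate_cohort(cfg)
    seg <- suppressMessages(segment_profiles(
      co$lrr, seg_params(gamma = 2, kmin = 5)))
    cx <- cohort_complexity(seg, co$clinical)
    truth <- unlist(lapply(co$patients,
                           function(p) p$aberrant_fraction)) * 100
    expect_lte(mean(abs(cx$samples$percent - truth)), 2)
  }
})

test_that("true differing fraction is computed on the breakpoint union", {
  a <- data.frame(chrom = "1", start = 1, end = 100, nA = 1L, nB = 1L)
  b <- data.frame(chrom = "1", start = c(1, 41), end = c(40, 100),
                  nA = c(1L, 2L), nB = c(1L, 1L))
  expect_equal(true_differing_fraction(a, b), 0.6)
  expect_equal(true_differing_fraction(a, a), 0)
  # a cnLOH difference is copy neutral and does not count
  d <- data.frame(chrom = "1", start = 1, end = 100, nA = 0L, nB = 2L)
  expect_equal(true_differing_fraction(a, d), 0)
})
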