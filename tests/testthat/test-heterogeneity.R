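test_that("variance filter keeps atoms by strict cross-sample variance", {
  e <- rbind(c(0, 0, 0),          # zero variance: removed
             c(0, 0.4, 0),       # var 0.04  > 0.03: kept
             c(0, 0.3, 0))       # var 0.03: not strictly above, removed
  colnames(e) <- c("a", "b", "c")
  at <- make_atoms(e)
  kept <- variance_filter(at, 0.03)
  expect_equal(nrow(kept$atoms), 1L)
  expect_equal(kept$estimates[1, ], c(a = 0, b = 0.4, c = 0))
  expect_equal(attr(kept, "retained_fraction"), 1 / 3)

  # hand check of the two-sample case: var(c(0, 0.4)) = 0.08 (ddof = 1)
  at2 <- make_atoms(cbind(a = 0, b = 0.4))
  expect_equal(nrow(variance_filter(at2, 0.03)$atoms), 1L)

  # "none" disables filtering
  expect_equal(nrow(variance_filter(at, "none")$atoms), 3L)
  expect_error(variance_filter(make_atoms(cbind(a = 0, b = 0)), 0.03),
               "cutoff")
})

test_that("pairwise Euclidean distance follows the defining formula", {
  expect_equal(pairwise_euclidean(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pairwise_euclidean(c(0.3, 0), c(0, 0.4)), 0.5)
  # permutation invariance
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20); p <- sample(20)
  expect_equal(pairwise_euclidean(a[p], b[p]), pairwise_euclidean(a, b))
  # dimension scaling: a fixed per-atom difference replicated over k atoms
  # scales the distance by sqrt(k)
  d1 <- pairwise_euclidean(0.2, 0)
  for (k in c(4, 9, 25))
    expect_equal(pairwise_euclidean(rep(0.2, k), rep(0, k)), sqrt(k) * d1)
})

test_that("patient heterogeneity averages all deposit pairs", {
  # identical deposits: score 0 (variance from a third, different sample)
  e <- cbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  at <- make_atoms(e)
  r <- patient_heterogeneity(at, c("a", "b"), variance_cutoff = 0.03)
  expect_equal(r$score, 0)
  expect_equal(r$n_pairs, 1L)

  # single atom with values 0, 1, 3: pairwise distances 1, 3, 2 -> mean 2
  at2 <- make_atoms(cbind(a = 0, b = 1, c = 3))
  r2 <- patient_heterogeneity(at2, c("a", "b", "c"), "none")
  expect_equal(r2$score, 2)
  expect_equal(r2$n_pairs, 3L)

  # sample order invariance
  r3 <- patient_heterogeneity(at2, c("c", "a", "b"), "none")
  expect_equal(r3$score, r2$score)

  # single-deposit patients are reported absent, not zero
  r4 <- patient_heterogeneity(at2, "a", "none")
  expect_true(is.na(r4$score))
  expect_match(r4$reason, "fewer than two")
})

test_that("proportion-of-genome-different score is bp-weighted and strict", {
  # one 30 Mbp atom differing by 0.5 out of 100 Mbp total -> 30%
  e <- cbind(a = c(0.5, 0), b = c(0, 0))
  at <- make_atoms(e, length_bp = c(30e6, 70e6))
  r <- proportion_genome_different(at, c("a", "b"))
  expect_equal(r$score, 30)

  # identical profiles -> 0%
  expect_equal(proportion_genome_different(at, c("a", "a"))$score, 0)

  # difference exactly at the cutoff does not count (strict inequality)
  e2 <- cbind(a = c(0.1, 0), b = c(0, 0))
  expect_equal(proportion_genome_different(
    make_atoms(e2, c(30e6, 70e6)), c("a", "b"))$score, 0)

  # invariance to refining the atomic partition
  e3 <- cbind(a = c(0.5, 0), b = c(0, 0))
  at3 <- make_atoms(e3, c(30e6, 70e6))
  e3r <- cbind(a = c(0.5, 0.5, 0, 0), b = c(0, 0, 0, 0))
  at3r <- make_atoms(e3r, c(10e6, 20e6, 30e6, 40e6))
  expect_equal(proportion_genome_different(at3, c("a", "b"))$score,
               proportion_genome_different(at3r, c("a", "b"))$score)
})

test_that("longitudinal heterogeneity uses cross-resection pairs", {
  at <- make_atoms(cbind(f1 = 0, f2 = 1, s1 = 3))
  # 1 + 1 identical samples -> 0
  at0 <- make_atoms(cbind(f1 = c(1, 0), s1 = c(1, 0), x = c(0, 1)))
  expect_equal(longitudinal_heterogeneity(at0, "f1", "s1", 0.03)$score, 0)

  # 2 first + 1 second: exactly the 2 cross pairs |0-3|, |1-3| -> 2.5
  r <- longitudinal_heterogeneity(at, c("f1", "f2"), "s1", "none")
  expect_equal(r$n_pairs, 2L)
  expect_equal(r$score, mean(c(3, 2)))

  # all-pairs alternative additionally includes the within-resection pair
  r_all <- longitudinal_heterogeneity(at, c("f1", "f2"), "s1", "none",
                                      all_pairs = TRUE)
  expect_equal(r_all$n_pairs, 3L)
  expect_equal(r_all$score, mean(c(1, 3, 2)))
  expect_false(isTRUE(all.equal(r$score, r_all$score)))

  expect_true(is.na(longitudinal_heterogeneity(
    at, character(0), "s1", "none")$score))
})

test_that("ploidy-adjusted score works on absolute copy numbers", {
  seg <- function(s, nA, nB) data.frame(sample = s, chrom = "1", start = 1,
                                        end = 1e6, nA = nA, nB = nB,
                                        stringsAsFactors = FALSE)
  # identical profiles, equal ploidy -> 0
  ap <- allele_profiles(rbind(seg("a", 1L, 1L), seg("b", 1L, 1L)),
                        data.frame(sample = c("a", "b"), rho = 1,
                                   psi = c(2, 2)))
  expect_equal(ploidy_adjusted_heterogeneity(ap, c("a", "b"))$score, 0)

  # diploid vs genome-doubled: 0 after dividing by ploidy
  ap2 <- allele_profiles(rbind(seg("a", 1L, 1L), seg("b", 2L, 2L)),
                         data.frame(sample = c("a", "b"), rho = 1,
                                    psi = c(2, 4)))
  expect_equal(ploidy_adjusted_heterogeneity(ap2, c("a", "b"))$score, 0)

  # copies 2 vs 3 at psi = 2: |1 - 1.5| = 0.5 on the single atom
  ap3 <- allele_profiles(rbind(seg("a", 1L, 1L), seg("b", 1L, 2L)),
                         data.frame(sample = c("a", "b"), rho = 1,
                                    psi = c(2, 2)))
  expect_equal(ploidy_adjusted_heterogeneity(ap3, c("a", "b"))$score, 0.5)

  # samples without a profile are skipped
  expect_message(r <- ploidy_adjusted_heterogeneity(ap3, c("a", "b", "zz")),
                 "skipped")
  expect_equal(r$n_samples, 2L)
})

test_that("cancer-cell-fraction diversity averages absolute differences", {
  clin <- toy_clinical()
  clin$ccf <- c(0.3, 0.5, 0.6, NA)
  clin3 <- rbind(clin, data.frame(patient = "P1", sample = "e", resection = 1L,
                                  synchronous = 1L, chemo = 0L,
                                  tp53 = "wildtype", age = 60L, sex = "F",
                                  ccf = 0.9, pfs_time = 10, pfs_event = 1L,
                                  os_time = 15, os_event = 1L))
  expect_equal(ccf_diversity(as_cohort_table(clin3), "P1"),
               mean(c(0.2, 0.6, 0.4)))
  expect_equal(ccf_diversity(clin, "P1"), 0.2)
  # one usable pair after exclusion of a missing value
  clin$ccf <- c(0.5, NA, 0.6, NA)
  clin4 <- rbind(clin, data.frame(patient = "P1", sample = "e", resection = 1L,
                                  synchronous = 1L, chemo = 0L,
                                  tp53 = "wildtype", age = 60L, sex = "F",
                                  ccf = 0.7, pfs_time = 10, pfs_event = 1L,
                                  os_time = 15, os_event = 1L))
  expect_equal(ccf_diversity(as_cohort_table(clin4), "P1"), 0.2)
  expect_true(is.na(ccf_diversity(clin, "P2")))
})

test_that("scores are invariant to atom ordering", {
  set.seed(12)
  e <- matrix(rnorm(30 * 3, 0, 0.5), 30,
              dimnames = list(NULL, c("a", "b", "c")))
  at <- make_atoms(e)
  p <- sample(30)
  atp <- make_atoms(e[p, , drop = FALSE])
  expect_equal(patient_heterogeneity(at, c("a", "b", "c"), 0.03)$score,
               patient_heterogeneity(atp, c("a", "b", "c"), 0.03)$score)
  expect_equal(proportion_genome_different(at, c("a", "b"))$score,
               proportion_genome_different(atp, c("a", "b"))$score)
})
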