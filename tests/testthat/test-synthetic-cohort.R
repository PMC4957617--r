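test_that("config invariants are enforced", {
  expect_error(tiny_config(eaf = 1.2), "EAF")
  expect_error(tiny_config(sd = -1), "positive")
  # implied genetic variance exceeding the total variance is rejected
  expect_error(tiny_config(eaf = 0.5, beta = 2, sd = 1), "exceeds total variance")
  expect_error(two_snp_config(r2 = 1.4), "\\[0,1\\]")
})

test_that("same config and seed give byte-identical cohorts", {
  cfg <- igf_consortium_config(n = 80, n_studies = 3, tau2 = 0.01)
  a <- simulate_consortium(cfg, seed = 11)
  b <- simulate_consortium(cfg, seed = 11)
  expect_identical(a, b)
  c <- simulate_consortium(cfg, seed = 12)
  expect_false(identical(a$dosage, c$dosage))
})

test_that("null model at large n: EAF recovered and HWE satisfied", {
  co <- simulate_cohort(tiny_config(n = 1e6, eaf = 0.5), seed = 1)
  expect_equal(allele_stats(co$dosage[, 1])$eaf, 0.5, tolerance = 0.002)
  hw <- hwe_test(c(sum(co$dosage == 2), sum(co$dosage == 1), sum(co$dosage == 0)))
  expect_gt(hw$p, 1e-4)
})

test_that("marginals at n = 1e5 match the configured world within 3 MC SE", {
  n <- 1e5
  cfg <- tiny_config(n = n, eaf = 0.27, beta = 0.3, sd = 2, mean = 10,
                     outcome = list(prevalence = 0.2))
  co <- simulate_cohort(cfg, seed = 42)
  eaf_se <- sqrt(0.27 * 0.73 / (2 * n))
  expect_lt(abs(allele_stats(co$dosage[, 1])$eaf - 0.27), 3 * eaf_se)
  expect_lt(abs(mean(co$biomarkers[, 1]) - 10), 3 * 2 / sqrt(n))
  expect_equal(sd(co$biomarkers[, 1]), 2, tolerance = 0.02)
  expect_lt(abs(mean(co$disease) - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("log-normal biomarkers are generated on the log scale", {
  cfg <- tiny_config(n = 2e4, beta = 0.1, sd = 0.4, mean = 5.8, log_normal = TRUE)
  co <- simulate_cohort(cfg, seed = 5)
  expect_true(all(co$biomarkers > 0))
  lx <- log(co$biomarkers[, 1])
  expect_equal(mean(lx), 5.8, tolerance = 0.02)
  expect_equal(sd(lx), 0.4, tolerance = 0.01)
  expect_equal(analysis_biomarkers(co)[, 1], lx)
})

test_that("single-SNP variance algebra: R2 matches 2p(1-p)beta^2/SD^2", {
  # derived-EAF world: 2p(1-p) = R2 SD^2 / beta^2 with R2 = 4.98%,
  # SD = 265, beta = 94.78 gives p = 0.2647
  p <- (1 - sqrt(1 - 2 * 0.0498 * 265^2 / 94.78^2)) / 2
  expect_equal(p, 0.2647, tolerance = 1e-3)
  cfg <- tiny_config(n = 718, eaf = p, beta = 94.78, sd = 265, mean = 700)
  r2 <- vapply(200 + seq_len(60), function(s) {
    co <- simulate_cohort(cfg, seed = s)
    exposure_regression(co$dosage[, 1], co$biomarkers[, 1])$r2
  }, numeric(1))
  expect_equal(mean(r2), 2 * p * (1 - p) * 94.78^2 / 265^2, tolerance = 0.1)
})

test_that("LD targets are hit and r2 = 1 duplicates exactly", {
  set.seed(1)
  co <- simulate_cohort(two_snp_config(n = 5e4, r2 = 0.5), seed = 2)
  expect_equal(ld_r2(co$dosage[, 1], co$dosage[, 2]), 0.5, tolerance = 0.05)
  co1 <- simulate_cohort(two_snp_config(n = 200, r2 = 1), seed = 3)
  expect_identical(co1$dosage[, 1], co1$dosage[, 2])
  expect_equal(ld_r2(co1$dosage[, 1], co1$dosage[, 2]), 1.0)
})

test_that("infeasible LD targets error with the achievable bound", {
  expect_error(
    simulate_cohort(two_snp_config(n = 100, eaf = c(0.05, 0.5), r2 = 0.9), seed = 1),
    "achievable bound"
  )
  expect_error(
    simulate_cohort(two_snp_config(n = 100, eaf = c(0.1, 0.4), r2 = 1), seed = 1),
    "equal EAFs"
  )
})

test_that("consortium structure: labels, case-only fields, tau2 = 0 homogeneity", {
  cfg <- igf_consortium_config(n = 500, n_studies = 6, tau2 = 0)
  co <- simulate_consortium(cfg, seed = 9)
  expect_equal(nlevels(co$study), 6)
  expect_false(anyNA(co$study))
  # grade/stage/survival only among cases
  expect_true(all(is.na(co$grade[co$disease == 0])))
  expect_true(all(!is.na(co$grade[co$disease == 1])))
  expect_true(all(co$time[!is.na(co$time)] > 0))
  # no heterogeneity beyond sampling noise: a single-draw I2 is noisy, so
  # average over replicate consortia
  stats <- vapply(1:8, function(i) {
    cc <- simulate_consortium(cfg, seed = 100 + i)
    ps <- study_assoc_table(cc, "snp1", "case-control")
    mr <- pool(ps)
    c(i2 = mr$i2, fixed = mr$model == "fixed")
  }, numeric(2))
  expect_lt(mean(stats["i2", ]), 25)
  expect_gte(mean(stats["fixed", ]), 0.75)
})

test_that("n_studies = 1 consortium is identical to simulate_cohort", {
  cfg <- igf_consortium_config(n = 150, n_studies = 1)
  expect_identical(simulate_consortium(cfg, seed = 4),
                   simulate_cohort(cfg, seed = 4))
})

test_that("dosage noise stays in [0,2] and preserves the EAF", {
  cfg <- tiny_config(n = 2e4, eaf = 0.3, dosage_error = 30)
  co <- simulate_cohort(cfg, seed = 6)
  d <- co$dosage[, 1]
  expect_true(all(d >= 0 & d <= 2))
  expect_false(all(d == round(d)))
  expect_equal(mean(d) / 2, 0.3, tolerance = 0.02)
})

test_that("direct SNP-on-outcome pleiotropy switch shifts the genotype OR", {
  cfg_null <- tiny_config(n = 3e4, eaf = 0.3, outcome = list(prevalence = 0.3))
  cfg_pleio <- tiny_config(n = 3e4, eaf = 0.3,
                           outcome = list(prevalence = 0.3,
                                          snp_logor = c(s1 = 0.4)))
  a <- logistic_assoc(simulate_cohort(cfg_null, 7)$dosage[, 1],
                      simulate_cohort(cfg_null, 7)$disease)
  b <- logistic_assoc(simulate_cohort(cfg_pleio, 7)$dosage[, 1],
                      simulate_cohort(cfg_pleio, 7)$disease)
  expect_lt(abs(a$log_effect), 0.08)
  expect_equal(b$log_effect, 0.4, tolerance = 0.1)
})
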