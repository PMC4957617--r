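test_that("wald_ratio direct arithmetic oracle", {
  # beta_gx 2, scale_sd 4, OR_gy 1.1 -> exp((4/2) ln 1.1) = 1.21 exactly
  w <- wald_ratio(beta_gx = 2, log_gy = log(1.1), se_gy = 0.05, scale_sd = 4)
  expect_equal(w$effect, 1.21, tolerance = 1e-12)
  # null gene-outcome effect -> causal effect exactly 1
  w0 <- wald_ratio(beta_gx = 94.78, log_gy = 0, se_gy = 0.02, scale_sd = 265)
  expect_equal(w0$effect, 1.0)
  expect_error(wald_ratio(0, NA, 0.1, 0.05), "non-zero")
  expect_error(wald_ratio(2, NA, 0.1, 0.05, scale_sd = -1), "positive")
})

test_that("unit invariance: rescaling the exposure leaves the estimate unchanged", {
  for (c_unit in c(0.001, 1, 37.5)) {
    w1 <- wald_ratio(94.78, 14.44, log(1.05), 0.0243, scale_sd = 265,
                     se_method = "delta2")
    w2 <- wald_ratio(94.78 * c_unit, 14.44 * c_unit, log(1.05), 0.0243,
                     scale_sd = 265 * c_unit, se_method = "delta2")
    expect_equal(w2$causal_log_effect, w1$causal_log_effect, tolerance = 1e-12)
    expect_equal(w2$se, w1$se, tolerance = 1e-12)
    expect_equal(w2$ci, w1$ci, tolerance = 1e-12)
  }
})

test_that("se methods are ordered and Fieller converges to delta as F grows", {
  b <- 0.5; lg <- 0.2; sg <- 0.05
  d1 <- wald_ratio(b, 0.05, lg, sg, se_method = "delta1")
  d2 <- wald_ratio(b, 0.05, lg, sg, se_method = "delta2")
  expect_gt(d2$se, d1$se)
  # weak-ish instrument: Fieller interval contains the delta1 interval
  fw <- suppressWarnings(wald_ratio(b, 0.2, lg, sg, se_method = "fieller"))
  dw <- suppressWarnings(wald_ratio(b, 0.2, lg, sg, se_method = "delta1"))
  expect_lt(fw$ci[1], dw$ci[1])
  expect_gt(fw$ci[2], dw$ci[2])
  # strong instrument: Fieller ~ delta1
  fs <- wald_ratio(b, 0.001, lg, sg, se_method = "fieller")
  ds <- wald_ratio(b, 0.001, lg, sg, se_method = "delta1")
  expect_equal(log(fs$ci), log(ds$ci), tolerance = 1e-3)
  # hopeless instrument: unbounded interval, flagged
  msgs <- capture_warnings(fu <- wald_ratio(0.05, 0.2, lg, sg, se_method = "fieller"))
  expect_true(any(grepl("unbounded", msgs)))
  expect_true(any(grepl("weak instrument", msgs)))
  expect_equal(fu$ci, c(0, Inf))
  expect_warning(wald_ratio(0.1, 0.2, lg, sg), "weak instrument")
})

test_that("harmonize handles orientation, strand and palindromes", {
  expo <- list(effect_allele = "A", other_allele = "G", beta = 94.78)
  same <- list(effect_allele = "A", other_allele = "G", log_effect = 0.05, eaf = 0.27)
  h <- harmonize(expo, same)
  expect_false(h$flipped)
  expect_equal(h$outcome$log_effect, 0.05)
  swapped <- list(effect_allele = "G", other_allele = "A", log_effect = 0.05, eaf = 0.73)
  h <- harmonize(expo, swapped)
  expect_true(h$flipped)
  expect_equal(h$outcome$log_effect, -0.05)
  expect_equal(h$outcome$eaf, 0.27)
  expect_equal(h$outcome$effect_allele, "A")
  # strand complement: A/G vs T/C
  comp <- list(effect_allele = "T", other_allele = "C", log_effect = 0.05)
  h <- harmonize(expo, comp)
  expect_true(h$strand_flipped)
  expect_false(h$flipped)
  # palindromic A/T flagged ambiguous
  pal_x <- list(effect_allele = "A", other_allele = "T", beta = 1)
  pal_y <- list(effect_allele = "A", other_allele = "T", log_effect = 0.1)
  expect_warning(h <- harmonize(pal_x, pal_y), "palindromic")
  expect_true(h$ambiguous)
  bad <- list(effect_allele = "A", other_allele = "C", log_effect = 0.1)
  expect_error(harmonize(expo, bad), "incompatible")
})

test_that("mr_report excludes weak instruments and keeps instruments separate", {
  ins <- data.frame(snp = c("s1", "s1", "s2"),
                    biomarker = c("IGF2", "IGFBP3", "IGF2"),
                    beta = c(90, 200, 60), se = c(15, 55, 30),
                    F = c(36, 13, 4))
  out <- data.frame(snp = c("s1", "s1", "s2"),
                    outcome = c("grade", "case-control", "grade"),
                    beta = c(0.049, 0.01, 0.03), se = c(0.024, 0.02, 0.03))
  sd_table <- c(IGF2 = 265, IGFBP3 = 1000)
  rep <- suppressMessages(mr_report(ins, out, sd_table))
  # s2 weak (F = 4) excluded; s1 has two exposures x two outcomes = 4 rows
  expect_equal(nrow(rep), 4)
  expect_false("s2" %in% rep$snp)
  expect_setequal(unique(rep$exposure), c("IGF2", "IGFBP3"))
  # two instruments for one exposure stay separate rows, never pooled
  ins2 <- rbind(ins[1, ], transform(ins[1, ], snp = "s3", F = 20))
  out2 <- data.frame(snp = c("s1", "s3"), outcome = "grade",
                     beta = 0.049, se = 0.024)
  rep2 <- mr_report(ins2, out2, sd_table)
  expect_equal(nrow(rep2), 2)
  # empty intersection warns and returns an empty table
  expect_warning(e <- suppressMessages(
    mr_report(ins[3, ], out[1:2, ], sd_table)), "empty")
  expect_equal(nrow(e), 0)
})

test_that("two-sample MR from the bundled literature summary statistics", {
  expo <- read_sumstats(system.file("extdata", "literature_exposure_sumstats.tsv",
                                    package = "igfmr"))
  outc <- read_sumstats(system.file("extdata", "literature_grade_sumstats.tsv",
                                    package = "igfmr"))
  h <- harmonize(as.list(expo[expo$trait == "IGF2", ]), as.list(outc[1, ]))
  expect_false(h$flipped)
  w <- wald_ratio(h$exposure$beta, h$exposure$se, h$outcome$beta, h$outcome$se,
                  scale_sd = 265)
  expect_equal(w$effect, 1.146, tolerance = 1e-3)
  expect_equal(w$ci, c(1.00, 1.31), tolerance = 0.005)
})

test_that("simulation recovery: per-SD causal log-OR in the rare-outcome regime", {
  # strong instrument, no pleiotropy, 5% prevalence; truth 0.2 per SD
  expo_cfg <- tiny_config(n = 718, eaf = 0.3, beta = 0.3, sd = 1)
  out_cfg <- tiny_config(n = 12000, eaf = 0.3, beta = 0.3, sd = 1,
                         outcome = list(prevalence = 0.05, logor = 0.2))
  est <- vapply(seq_len(60), function(i) {
    e <- simulate_cohort(expo_cfg, seed = 9000 + i)
    o <- simulate_cohort(out_cfg, seed = 19000 + i)
    gx <- exposure_regression(e$dosage[, 1], e$biomarkers[, 1])
    gy <- logistic_assoc(o$dosage[, 1], o$disease)
    wald_ratio(gx$beta, gx$se, gy$log_effect, gy$se,
               scale_sd = sd(e$biomarkers[, 1]))$causal_log_effect
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.2), max(3 * mc_se, 0.1 * 0.2))
})
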