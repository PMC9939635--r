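test_that("exposure draws reproduce the configured GM and GSD", {
  cfg <- exposure_config(n_subjects = 20000, seed = 11)
  co <- generate_cohort(cfg)
  bpb <- co$exposures[co$exposures$component == "BPb", ]
  expect_equal(exp(mean(log(bpb$value))), 8.84, tolerance = 0.02)
  expect_equal(exp(sd(log(bpb$value))), 1.56, tolerance = 0.02)
})

test_that("a degenerate GSD of 1 collapses a cell onto its GM", {
  params <- exposure_defaults()
  params$gsd[params$component == "BPb"] <- 1
  co <- generate_cohort(exposure_config(params, n_subjects = 50, seed = 2))
  bpb <- co$exposures[co$exposures$component == "BPb", ]
  expect_equal(bpb$value, rep(8.84, 50))
})

test_that("same-metal media correlate at the configured latent rho", {
  cfg <- exposure_config(n_subjects = 50000, cross_media_rho = 0.6, seed = 3)
  m <- exposure_matrix(generate_cohort(cfg)$exposures, lod_policy = "as_stored")
  expect_equal(cor(log(m[, "BPb"]), log(m[, "UPb"])), 0.6, tolerance = 0.035)
  expect_equal(cor(log(m[, "HMn"]), log(m[, "SMn"])), 0.6, tolerance = 0.035)
  # different metals share no latent factor
  expect_lt(abs(cor(log(m[, "BPb"]), log(m[, "BCu"]))), 0.03)
})

test_that("censoring frequency is monotone in the LOD and values are stored as drawn", {
  base <- exposure_defaults()
  freqs <- sapply(c(0.5, 1, 2), function(f) {
    params <- base
    params$lod <- params$lod * f
    co <- generate_cohort(exposure_config(params, n_subjects = 2000, seed = 9))
    mean(co$exposures$censored)
  })
  expect_true(all(diff(freqs) >= 0))
  # the drawn value is kept even when censored
  co <- generate_cohort(exposure_config(n_subjects = 2000, seed = 9))
  cens <- co$exposures[co$exposures$censored, ]
  expect_true(all(cens$value > 0 & cens$value < cens$lod))
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- exposure_config(n_subjects = 40, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$exposures, b$exposures)
  expect_identical(a$burden, b$burden)
  ta <- generate_timeseries(a, n_rois = 10, n_timepoints = 60, n_modules = 2, seed = 5)
  tb <- generate_timeseries(b, n_rois = 10, n_timepoints = 60, n_modules = 2, seed = 5)
  expect_identical(ta$subjects[[3]]$data, tb$subjects[[3]]$data)
})

test_that("configuration errors are caught", {
  params <- exposure_defaults()
  params$gm[1] <- -1
  expect_error(exposure_config(params), "positive")
  params <- exposure_defaults()
  params$gsd[1] <- 0.5
  expect_error(exposure_config(params), "geometric standard deviations")
  expect_error(exposure_config(cross_media_rho = 1), "cross_media_rho")
  expect_error(ground_truth(level2_weights = c(Mn = 1, Pb = 1, Cr = 0, Cu = 0)),
               "simplex")
  expect_error(ground_truth(noise_sd = -0.1), "noise_sd")
})

test_that("cohort structure: 16 components per subject, burden in [0, 1]", {
  co <- generate_cohort(exposure_config(n_subjects = 35, seed = 4))
  expect_equal(nrow(co$exposures), 35 * 16)
  counts <- table(co$exposures$subject_id)
  expect_true(all(counts == 16))
  expect_true(all(co$burden >= 0 & co$burden <= 1))
  expect_true(all(co$covariates$age >= 15 & co$covariates$age <= 25))
  expect_true(all(co$covariates$sex %in% 0:1))
})

test_that("direct-mode outcomes recover the injected effect", {
  # noiseless: OLS on the true index returns beta exactly
  tr0 <- ground_truth(noise_sd = 0)
  co <- generate_cohort(exposure_config(n_subjects = 300, seed = 5), tr0)
  oc <- generate_direct_outcomes(co, seed = 6)
  fit <- lm(oc$ge ~ co$burden + I(co$covariates$age - 20) + co$covariates$sex)
  expect_equal(unname(coef(fit)[2]), -0.076, tolerance = 1e-10)
  fit_le <- lm(oc$le_mean ~ co$burden + I(co$covariates$age - 20) + co$covariates$sex)
  expect_equal(unname(coef(fit_le)[2]), -0.048, tolerance = 1e-10)
  # zero effect, no noise: outcomes flat up to covariate terms
  tr_flat <- ground_truth(noise_sd = 0, beta_ge = 0, age_effect = 0, sex_effect = 0)
  oc2 <- generate_direct_outcomes(
    generate_cohort(exposure_config(n_subjects = 50, seed = 7), tr_flat), seed = 8)
  expect_equal(oc2$ge, rep(tr_flat$intercept_ge, 50))
  # with noise: OLS recovers beta within 0.01 at n = 500
  co3 <- generate_cohort(exposure_config(n_subjects = 500, seed = 9))
  oc3 <- generate_direct_outcomes(co3, seed = 10)
  fit3 <- lm(oc3$ge ~ co3$burden + I(co3$covariates$age - 20) + co3$covariates$sex)
  expect_lt(abs(unname(coef(fit3)[2]) - (-0.076)), 0.01)
})

test_that("time-series generator: structure, stationary blocks, coupling effect", {
  co <- generate_cohort(exposure_config(n_subjects = 3, seed = 1))
  ts <- generate_timeseries(co, n_rois = 20, n_timepoints = 600, n_modules = 4,
                            nuisance_scale = 0, seed = 2)
  s <- ts$subjects[[1]]
  expect_equal(dim(s$data), c(600L, 20L))
  expect_equal(ncol(s$motion), 6L)
  # block structure recoverable from the empirical correlation at T = 600
  cc <- cor(s$data)
  same <- outer(ts$modules, ts$modules, `==`) & upper.tri(cc)
  diff <- (!outer(ts$modules, ts$modules, `==`)) & upper.tri(cc)
  thr <- (0.65 + max(0.45 - 0.25 * co$burden[1], 0)) / 2
  expect_true(all(cc[same] > thr))
  expect_true(all(cc[diff] < thr))
  # covariance is symmetric PSD
  cv <- cov(s$data)
  expect_lt(max(abs(cv - t(cv))), 1e-12)
  expect_gt(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # out-of-range coupling errors
  expect_error(
    generate_timeseries(co, n_rois = 10, n_timepoints = 50, n_modules = 2,
                        coupling_base = 0.9, coupling_slope = 0.3,
                        within_coupling = 0.95, seed = 3),
    "coupling"
  )
})

test_that("injected coupling slope drives the burden-efficiency association", {
  co <- generate_cohort(exposure_config(n_subjects = 60, seed = 2))
  ts <- generate_timeseries(co, n_rois = 30, n_timepoints = 240, n_modules = 3,
                            seed = 3)
  met <- subject_metrics(ts)
  ct <- cor.test(co$burden, met$ge)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # with a zero slope the association vanishes
  ts0 <- generate_timeseries(co, n_rois = 30, n_timepoints = 240, n_modules = 3,
                             coupling_slope = 0, seed = 3)
  met0 <- subject_metrics(ts0)
  expect_gt(cor.test(co$burden, met0$ge)$p.value, 0.05)
})
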