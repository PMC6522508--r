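test_that("hazard calibration inverts exponential survival", {
  expect_equal(calibrate_hazard(1, 90), 0)
  # hand-derived: -ln(0.959)/90 and -ln(0.434)/14
  expect_equal(calibrate_hazard(0.959, 90), 4.652e-4, tolerance = 1e-4)
  expect_equal(calibrate_hazard(0.434, 14), 5.9622e-2, tolerance = 1e-4)
  # the calibrated rate reproduces the survival at the horizon exactly
  h <- calibrate_hazard(0.641, 90)
  expect_equal(exp(-h * 90), 0.641)
  expect_error(calibrate_hazard(0, 90), "0, 1")
  expect_error(calibrate_hazard(1.2, 90), "0, 1")
  expect_error(calibrate_hazard(0.5, 0), "> 0")
})

test_that("default configuration states the published world", {
  cfg <- cohort_config()
  expect_equal(cfg$hcc_prevalence, 0.476)
  expect_equal(cfg$n, 2248L)
  st <- cfg$strata
  # bands partition [6, 40]; the <=20 sub-bands pool to 95.9% at 90 days
  expect_equal(st$meld_lo[1], 6L)
  expect_equal(st$meld_hi[nrow(st)], 40L)
  expect_true(all(st$meld_lo[-1] == st$meld_hi[-nrow(st)] + 1L))
  s90 <- exp(-st$daily_hazard * 90)
  expect_equal((8 * s90[1] + 7 * s90[2]) / 15, 0.959, tolerance = 1e-10)
  expect_equal(s90[3], 0.641, tolerance = 1e-10)
  s14 <- exp(-st$daily_hazard * 14)
  expect_equal(s14[4], 0.640, tolerance = 1e-10)
  expect_equal(s14[5], 0.434, tolerance = 1e-10)
  expect_equal(cfg$hcc_shift$shift, c(4L, 5L))
  # invalid configurations are rejected
  bad <- cfg$strata[-2, ]
  expect_error(cohort_config(strata = bad), "partition")
  expect_error(cohort_config(hcc_prevalence = 1.2), "0, 1")
  expect_error(cohort_config(n = 0), "n must")
})

test_that("generator is deterministic per seed and distinct across seeds", {
  a <- simulate_cohort(cohort_config(n = 300, seed = 9))
  b <- simulate_cohort(cohort_config(n = 300, seed = 9))
  expect_identical(a, b)
  c <- simulate_cohort(cohort_config(n = 300, seed = 10))
  expect_false(identical(a$follow_up_days, c$follow_up_days))
})

test_that("generated laboratory values reproduce the sampled MELD exactly", {
  reg <- simulate_cohort(cohort_config(n = 2000, seed = 13))
  m <- compute_meld(reg$creatinine, reg$bilirubin, reg$inr,
                    reg$dialysis_sessions_last_week, reg$cvvh_24h)
  expect_true(all(m$score >= 6L & m$score <= 40L))
  expect_true(all(reg$creatinine <= 4 & reg$creatinine >= 1))
  # the whole registry validates and classifies
  expect_s3_class(reg, "liver_registry")
  expect_false(anyNA(derive_outcome(reg)$event))
})

test_that("no censoring mechanism means every record is an event", {
  cfg <- cohort_config(n = 150, seed = 3, censor_daily_hazard = 0,
                       max_follow_up_days = Inf, accrual_days = 1095)
  reg <- simulate_cohort(cfg)
  expect_true(all(derive_outcome(reg)$event))
  expect_true(all(reg$removal_reason %in% c("death", "deterioration")))
})

test_that("covariate marginals concentrate at their configured values", {
  reg <- simulate_cohort(cohort_config(n = 4000, seed = 17))
  se <- function(p) sqrt(p * (1 - p) / 4000)
  expect_lt(abs(mean(reg$hcc) - 0.476), 4 * se(0.476))
  expect_lt(abs(mean(reg$sex == "M") - 0.734), 4 * se(0.734))
  expect_lt(abs(mean(reg$blood_type == "A") - 0.345), 4 * se(0.345))
  expect_lt(abs(mean(reg$etiology == "hbv") - 0.710), 4 * se(0.710))
  expect_lt(abs(mean(reg$ctp_score >= 10) - 0.417), 4 * se(0.417))
  # MELD marginal: mean near the published 17.1
  m <- add_meld(reg)$meld
  expect_lt(abs(mean(m) - 17.1), 1.0)
})

test_that("each stratum's KM estimate sits within Monte-Carlo error of its calibration", {
  reg <- add_meld(simulate_cohort(cohort_config(n = 8000, seed = 19)))
  out <- derive_outcome(reg)
  nh <- !reg$hcc
  targets <- list(c(6, 13, 90, 0.980), c(14, 20, 90, 0.935),
                  c(21, 30, 90, 0.641), c(31, 37, 14, 0.640),
                  c(38, 40, 14, 0.434))
  for (b in targets) {
    sel <- nh & reg$meld >= b[1] & reg$meld <= b[2]
    km <- km_fit(out$time_days[sel], out$event[sel])
    s <- km_survival_at(km, b[3])
    gse <- km$se[max(which(km$time <= b[3]))]
    expect_lt(abs(s - b[4]), 3 * gse)
  }
})

test_that("with zero HCC shift, HCC and non-HCC survival are exchangeable within bands", {
  cfg <- cohort_config(n = 6000, seed = 23,
                       hcc_shift = data.frame(meld_lo = c(6L, 14L),
                                              meld_hi = c(13L, 20L),
                                              shift = c(0L, 0L)))
  reg <- add_meld(simulate_cohort(cfg))
  out <- derive_outcome(reg)
  for (band in list(c(6, 13), c(14, 20))) {
    sel <- reg$meld >= band[1] & reg$meld <= band[2]
    lr <- logrank_test(out$time_days[sel], out$event[sel], reg$hcc[sel])
    expect_gt(lr$p_value, 0.01)
  }
})
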