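test_that("product-limit estimator matches hand computation and step evaluation", {
  # times 1..5 with events at 2 and 3: S(3) = (3/4)(2/3) = 0.5
  km <- km_fit(1:5, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(km$time, c(2, 3))
  expect_equal(km$n_risk, c(4, 3))
  expect_equal(km$surv, c(0.75, 0.5))
  expect_equal(km_survival_at(km, 2.5), 0.75)
  expect_equal(km_survival_at(km, 3), 0.5)
  expect_equal(km_survival_at(km, 0), 1)
  expect_equal(km_survival_at(km, 100), 0.5)  # step extension past last event
  # no events: S identically 1
  km0 <- km_fit(c(5, 8, 12), c(FALSE, FALSE, FALSE))
  expect_equal(km_survival_at(km0, c(0, 6, 50)), c(1, 1, 1))
  expect_error(km_fit(numeric(0), logical(0)), "empty")
  expect_error(km_fit(c(-1, 2), c(TRUE, TRUE)), "non-negative")
})

test_that("KM equals 1 - ECDF without censoring and ignores late censorings", {
  set.seed(21)
  for (rep in 1:10) {
    t <- round(rexp(40, 0.1), 2)
    km <- km_fit(t, rep(TRUE, 40))
    grid <- sort(unique(t))
    expect_equal(km_survival_at(km, grid), 1 - ecdf(t)(grid))
    # order invariance
    o <- sample(40)
    expect_equal(km_fit(t[o], rep(TRUE, 40))$surv, km$surv)
    # a censoring strictly before the first event never enters a risk set
    km2 <- km_fit(c(t, min(t) / 2), c(rep(TRUE, 40), FALSE))
    expect_equal(km2$surv, km$surv)
    expect_equal(km2$n_risk, km$n_risk)
  }
})

test_that("KM curve and Greenwood errors agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(33)
  d <- sim_exp_samples(200, 0.02, 0.01)
  km <- km_fit(d$time, d$event)
  sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  ours_at_sf <- km_survival_at(km, sf$time)
  expect_equal(ours_at_sf, sf$surv, tolerance = 1e-10)
  # survfit reports SE of log S; ours is Greenwood SE of S
  ev <- sf$n.event > 0
  expect_equal(km$se, (sf$surv * sf$std.err)[ev], tolerance = 1e-8)
})

test_that("log-rank statistic is zero for identical groups and matches hand sums", {
  t <- c(3, 8, 10, 15, 30)
  e <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
  expect_equal(sum(lr$observed - lr$expected), 0, tolerance = 1e-12)
  # hand-computed hypergeometric sums on {1,3} vs {2,4}, all events:
  # O1 = 2, E1 = 1/2 + 1/3 + 1/2 = 4/3, V = 1/4 + 2/9 + 1/4 = 13/18
  lr2 <- logrank_test(c(1, 3, 2, 4), rep(TRUE, 4), c(1, 1, 2, 2))
  expect_equal(lr2$statistic, (2 / 3)^2 / (13 / 18), tolerance = 1e-12)
  expect_equal(lr2$statistic, 0.61538, tolerance = 1e-4)
  expect_error(logrank_test(1:4, rep(TRUE, 4), rep("a", 4)), "2 non-empty")
  expect_error(logrank_test(1:4, rep(FALSE, 4), c(1, 1, 2, 2)), "no events")
})

test_that("log-rank agrees with survival::survdiff for 2 and 3 groups", {
  skip_if_not_installed("survival")
  set.seed(44)
  for (k in 2:3) {
    d <- do.call(rbind, lapply(seq_len(k), function(g)
      cbind(sim_exp_samples(60, 0.01 * g, 0.005), g = g)))
    lr <- logrank_test(d$time, d$event, d$g)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
    expect_equal(lr$statistic, unname(sd$chisq), tolerance = 1e-8)
    expect_equal(unname(lr$observed), unname(sd$obs), tolerance = 1e-10)
    expect_equal(unname(lr$expected), unname(sd$exp), tolerance = 1e-8)
    expect_equal(lr$df, k - 1L)
  }
})

test_that("log-rank is invariant to group relabeling", {
  set.seed(55)
  d <- rbind(cbind(sim_exp_samples(50, 0.02), g = "a"),
             cbind(sim_exp_samples(50, 0.05), g = "b"))
  lr1 <- logrank_test(d$time, d$event, d$g)
  lr2 <- logrank_test(d$time, d$event, ifelse(d$g == "a", "z", "y"))
  expect_equal(lr1$statistic, lr2$statistic, tolerance = 1e-10)
})

test_that("null log-rank p-values are approximately uniform", {
  set.seed(66)
  p <- replicate(400, {
    d <- rbind(cbind(sim_exp_samples(50, 0.02), g = 1),
               cbind(sim_exp_samples(50, 0.02), g = 2))
    logrank_test(d$time, d$event, d$g)$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
  rej <- mean(p < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("permutation p-value matches the asymptotic one at moderate n", {
  set.seed(77)
  d <- rbind(cbind(sim_exp_samples(60, 0.02), g = 1),
             cbind(sim_exp_samples(60, 0.045), g = 2))
  asym <- logrank_test(d$time, d$event, d$g)$p_value
  perm <- permutation_logrank(d$time, d$event, d$g, n_perm = 1999, seed = 3)
  expect_lt(abs(perm$p_value - asym),
            0.02 + 3 * sqrt(asym * (1 - asym) / 2000))
  # determinism given seed
  perm2 <- permutation_logrank(d$time, d$event, d$g, n_perm = 1999, seed = 3)
  expect_identical(perm$p_value, perm2$p_value)
  expect_error(permutation_logrank(d$time, d$event, d$g, n_perm = 0), "n_perm")
})
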