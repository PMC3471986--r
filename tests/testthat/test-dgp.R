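test_that("baseline covariates have the designed marginal distributions", {
  set.seed(11)
  n <- 1e5
  X <- generate_covariates(n)
  for (j in 1:3)
    expect_lt(abs(mean(X[, j]) - 0.5), 3 * sqrt(0.25 / n))
  for (j in 4:6) {
    expect_lt(abs(mean(X[, j])), 3 / sqrt(n))
    expect_lt(abs(stats::var(X[, j]) - 1), 0.05)
  }
  set.seed(42); a <- generate_covariates(1)
  set.seed(42); b <- generate_covariates(1)
  expect_identical(a, b)
  expect_error(generate_covariates(0), "n")
})

test_that("intercept calibration matches logit closed forms and hits the target", {
  null_model <- treatment_model(or_weak = 1, or_medium = 1, or_strong = 1)
  set.seed(5)
  expect_lt(abs(calibrate_treatment_intercept(0.5, null_model, 1e4)), 0.01)
  expect_lt(abs(calibrate_treatment_intercept(0.25, null_model, 1e4) -
                  log(0.25 / 0.75)), 0.02)
  expect_error(calibrate_treatment_intercept(0, null_model), "between 0 and 1")

  # independent Monte Carlo validation on a fresh covariate sample
  tm <- treatment_model()
  set.seed(7)
  b0 <- calibrate_treatment_intercept(0.10, tm, calibration_n = 5e5)
  Xv <- generate_covariates(5e5)
  z <- assign_treatment(Xv, treatment_model(intercept = b0))
  expect_lt(abs(mean(z) - 0.10), 0.003)
})

test_that("treatment assignment draws subject-specific Bernoulli indicators", {
  expect_error(assign_treatment(generate_covariates(10), treatment_model()),
               "calibrate")
  set.seed(3)
  X <- generate_covariates(5000)
  null_model <- treatment_model(1, 1, 1, intercept = 0)
  expect_lt(abs(mean(assign_treatment(X, null_model)) - 0.5), 0.03)
  tm <- treatment_model()
  set.seed(8)
  tm$intercept <- calibrate_treatment_intercept(0.25, tm, 2e5)
  z <- assign_treatment(generate_covariates(5000), tm)
  expect_lt(abs(mean(z) - 0.25), 0.02)
})

test_that("treatment waiting times follow the designed Weibull", {
  mdl <- treatment_time_model()
  # analytic median: scale * (log 2)^(1/shape) = 100 days
  expect_lt(abs(mdl$scale * log(2)^(1 / mdl$shape) - 100), 0.1)
  set.seed(21)
  tt <- draw_treatment_times(rep(1L, 1e5), mdl)
  expect_lt(abs(median(tt) - 100) / 100, 0.05)
  # S(scale) = exp(-1): the 63.2th percentile sits at the scale parameter
  expect_lt(abs(quantile(tt, 1 - exp(-1)) - mdl$scale) / mdl$scale, 0.05)
  mixed <- draw_treatment_times(c(0L, 1L), mdl)
  expect_true(is.na(mixed[1]) && is.finite(mixed[2]))
})

test_that("event-time inversion obeys its closed forms", {
  om <- outcome_model(hazard_ratio = 2)
  X0 <- matrix(0, 1, 6, dimnames = list(NULL, paste0("x", 1:6)))
  # unit cumulative hazard at LP = 0: T = (1/rate)^(1/shape)
  t_unit <- simulate_event_times_fixed(X0, 0L, om, e = 1)
  expect_equal(t_unit, (1 / om$rate)^(1 / om$shape), tolerance = 1e-12)
  # proportional-hazards scaling: adding log 2 to the LP scales every
  # quantile by 2^(-1/shape)
  set.seed(31)
  Xn <- matrix(0, 100, 6, dimnames = list(NULL, paste0("x", 1:6)))
  e <- rexp(100)
  t_untr <- simulate_event_times_fixed(Xn, rep(0L, 100), om, e = e)
  t_tr <- simulate_event_times_fixed(Xn, rep(1L, 100), om, e = e)
  expect_equal(t_tr / t_untr, rep(2^(-1 / om$shape), 100), tolerance = 1e-10)
})

test_that("generated event times match the analytic survival function", {
  om <- outcome_model(hazard_ratio = 2)
  set.seed(41)
  n <- 2e4
  X0 <- matrix(0, n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  tt <- simulate_event_times_fixed(X0, rep(0L, n), om)
  ks <- stats::ks.test(tt, function(t) 1 - exp(-om$rate * t^om$shape))
  expect_gt(ks$p.value, 0.01)
})

test_that("untreated-population event times have the designed marginal quantiles", {
  om <- outcome_model(hazard_ratio = 2)
  set.seed(51)
  X <- generate_covariates(1e5)
  tt <- simulate_event_times_fixed(X, rep(0L, 1e5), om)
  expect_lt(abs(median(tt) - 1000) / 1000, 0.15)
  expect_lt(abs(quantile(tt, 0.25) - 53) / 53, 0.15)
})

test_that("time-dependent generator reduces to the fixed generator in its limits", {
  n <- 200
  set.seed(61)
  X <- generate_covariates(n)
  e <- rexp(n)
  z <- rep(1L, n)
  om0 <- outcome_model(hazard_ratio = 1)
  t0 <- rweibull(n, 0.25, 433.2097)
  # no treatment effect: the hazard step is invisible
  expect_equal(simulate_event_times_timedep(X, z, t0, om0, e = e),
               simulate_event_times_fixed(X, rep(0L, n), om0, e = e),
               tolerance = 1e-10)
  # immediate treatment: identical to fixed exposure with the treated LP
  om2 <- outcome_model(hazard_ratio = 2)
  expect_equal(simulate_event_times_timedep(X, z, rep(0, n), om2, e = e),
               simulate_event_times_fixed(X, z, om2, e = e),
               tolerance = 1e-10)
  # untreated subjects never see the step
  expect_equal(simulate_event_times_timedep(X, rep(0L, n), rep(NA_real_, n),
                                            om2, e = e),
               simulate_event_times_fixed(X, rep(0L, n), om2, e = e),
               tolerance = 1e-10)
})

test_that("competing-events generator doubles the hazard and assigns fair causes", {
  om <- outcome_model(hazard_ratio = 2)
  n <- 2e4
  set.seed(71)
  X <- generate_covariates(n)
  z <- rep(0L, n)
  e <- rexp(n)
  out <- simulate_event_times_competing(X, z, om, e = e)
  t_single <- simulate_event_times_fixed(X, z, om, e = e)
  # doubling the rate scales all times by 2^(-1/shape)
  expect_equal(out$time / t_single, rep(2^(-1 / om$shape), n),
               tolerance = 1e-10)
  expect_lt(abs(mean(out$cause == "primary") - 0.5), 3 * sqrt(0.25 / n))
  # cause labels independent of event times
  ct <- stats::cor.test(out$time, as.integer(out$cause == "primary"))
  expect_gt(ct$p.value, 0.01)
})

test_that("Type II censoring stops follow-up at the k-th order statistic", {
  res <- apply_type2_censoring(c(10, 20, 30, 40), 0.25)
  expect_equal(res$observed_time, c(10, 10, 10, 10))
  expect_equal(res$event, c(1L, 0L, 0L, 0L))
  res <- apply_type2_censoring(c(3, 1, 2), 1)
  expect_equal(res$event, c(1L, 1L, 1L))
  expect_equal(res$observed_time, c(3, 1, 2))
  # exact event counts, including ties at the threshold (index order)
  set.seed(81)
  res <- apply_type2_censoring(rexp(5000), 0.05)
  expect_identical(sum(res$event), 250L)
  res <- apply_type2_censoring(c(5, 5, 5, 9), 0.5)
  expect_equal(res$event, c(1L, 1L, 0L, 0L))
  expect_equal(res$observed_time, c(5, 5, 5, 5))
  expect_error(apply_type2_censoring(c(1, 2, 3), 0.1), "event")
})

test_that("simulated cohorts satisfy their structural invariants", {
  tm <- treatment_model()
  set.seed(91)
  b0 <- calibrate_treatment_intercept(0.25, tm, 2e5)
  for (s in c("A", "B", "C")) {
    sc <- make_scenario(s, 2, 0.25, 0.10)
    cohort <- simulate_cohort(sc, b0)
    expect_identical(nrow(cohort), 5000L)
    if (s == "B") {
      # treated subjects whose latent event preceded their treatment time
      # are recorded as never treated, so the ever-treated fraction falls
      # below the assigned prevalence
      expect_lt(mean(cohort$treated), 0.25)
      expect_gt(mean(cohort$treated), 0.02)
    } else {
      expect_lt(abs(mean(cohort$treated) - 0.25), 0.03)
    }
    expect_true(all(cohort$observed_time <= cohort$latent_time + 1e-12))
    n_any <- if (s == "C") 1000L else 500L
    expect_identical(sum(cohort$event), n_any)
    expect_true(all(is.na(cohort$cause[cohort$event == 0L])))
    if (s == "B") {
      # treated subjects received treatment before their latent event
      trt <- cohort$treated == 1L
      expect_true(all(is.finite(cohort$treatment_time[trt])))
      expect_true(all(cohort$treatment_time[trt] <= cohort$latent_time[trt]))
      expect_true(all(is.na(cohort$treatment_time[!trt])))
    } else {
      expect_true(all(is.na(cohort$treatment_time)))
    }
    if (s == "C") {
      expect_true(all(cohort$cause[cohort$event == 1L] %in%
                        c("primary", "competing")))
    }
  }
})
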