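#' Treatment-selection model
#'
#' Logistic model for confounded treatment assignment at baseline. Six
#' baseline covariates enter in weak/medium/strong pairs: one binary and one
#' continuous covariate per strength tier, with odds ratios 1.10 (weak:
#' `x1`, `x4`), 1.50 (medium: `x2`, `x5`) and 2 (strong: `x3`, `x6`).
#' The intercept controls the marginal prevalence of treatment and is set
#' by [calibrate_treatment_intercept()].
#'
#' @param or_weak,or_medium,or_strong Odds ratios for the weak, medium and
#'   strong selection effects.
#' @param intercept Log-odds intercept; `NA` until calibrated.
#' @return An object of class `ncc_treatment_model`.
#' @seealso [assign_treatment()], [calibrate_treatment_intercept()]
#' @export
treatment_model <- function(or_weak = 1.10, or_medium = 1.50, or_strong = 2,
                            intercept = NA_real_) {
  structure(
    list(intercept = intercept,
         coef = c(x1 = log(or_weak), x2 = log(or_medium), x3 = log(or_strong),
                  x4 = log(or_weak), x5 = log(or_medium), x6 = log(or_strong))),
    class = "ncc_treatment_model")
}

#' Cox-Weibull outcome model
#'
#' Proportional-hazards model with cumulative baseline hazard
#' \eqn{H_0(t) = \lambda t^{\nu}} (default \eqn{\nu = 0.45},
#' \eqn{\lambda = 0.01}, time in days). Covariates enter in the same
#' weak/medium/strong pairs as the treatment-selection model, with hazard
#' ratios 1.25, 2 and 3; `hazard_ratio` is the treatment effect
#' \eqn{e^{\beta_{treat}}}. Under these defaults an untreated population has
#' a marginal event-time median of about 1000 days and a 25th percentile of
#' about 53 days.
#'
#' @param hazard_ratio True treatment hazard ratio.
#' @param hr_weak,hr_medium,hr_strong Covariate hazard ratios by tier.
#' @param shape,rate Weibull cumulative-hazard parameters \eqn{\nu} and
#'   \eqn{\lambda}.
#' @return An object of class `ncc_outcome_model`.
#' @export
outcome_model <- function(hazard_ratio, hr_weak = 1.25, hr_medium = 2,
                          hr_strong = 3, shape = 0.45, rate = 0.01) {
  stopifnot(hazard_ratio > 0, shape > 0, rate > 0)
  structure(
    list(shape = shape, rate = rate, beta_treat = log(hazard_ratio),
         coef = c(x1 = log(hr_weak), x2 = log(hr_medium), x3 = log(hr_strong),
                  x4 = log(hr_weak), x5 = log(hr_medium), x6 = log(hr_strong))),
    class = "ncc_outcome_model")
}

#' Waiting-time model for treatment initiation
#'
#' Weibull distribution (survival parameterisation,
#' \eqn{S(t) = \exp\{-(t/\mathrm{scale})^{\mathrm{shape}}\}}) for the time
#' from cohort entry to treatment initiation among subjects assigned to
#' treatment. The defaults give a median time to treatment of 100 days.
#'
#' @param shape,scale Weibull shape and scale (days).
#' @return An object of class `ncc_treatment_time_model`.
#' @export
treatment_time_model <- function(shape = 0.25, scale = 433.2097) {
  stopifnot(shape > 0, scale > 0)
  structure(list(shape = shape, scale = scale),
            class = "ncc_treatment_time_model")
}

#' Simulate baseline covariates
#'
#' Draws six mutually independent baseline covariates per subject: `x1`-`x3`
#' Bernoulli(0.5) and `x4`-`x6` standard normal.
#'
#' @param n Number of subjects (>= 1).
#' @return Numeric matrix with `n` rows and columns `x1`..`x6`.
#' @export
generate_covariates <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single integer >= 1")
  n <- as.integer(n)
  X <- cbind(stats::rbinom(n, 1L, 0.5), stats::rbinom(n, 1L, 0.5),
             stats::rbinom(n, 1L, 0.5), stats::rnorm(n), stats::rnorm(n),
             stats::rnorm(n))
  colnames(X) <- paste0("x", 1:6)
  X
}

## linear predictor over the six covariates
.lp <- function(X, coef) drop(X %*% coef)

#' Calibrate the treatment-model intercept to a target prevalence
#'
#' Finds the logistic intercept for which the marginal probability of
#' treatment equals `target_prevalence`, by bisection against the mean of
#' `plogis(intercept + lp)` over a fixed calibration sample of covariate
#' draws. The map from intercept to marginal prevalence is strictly
#' monotone, so bisection always converges.
#'
#' @param target_prevalence Desired marginal treatment prevalence, in (0, 1).
#' @param model An [treatment_model()] object.
#' @param calibration_n Size of the covariate calibration sample (drawn from
#'   the current RNG stream).
#' @param tol Tolerance on the achieved prevalence.
#' @param max_iter Bisection iteration cap.
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_treatment_intercept <- function(target_prevalence, model,
                                          calibration_n = 1e6, tol = 1e-3,
                                          max_iter = 200L) {
  if (!is.finite(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1)
    stop("'target_prevalence' must lie strictly between 0 and 1")
  X <- generate_covariates(calibration_n)
  lp <- .lp(X, model$coef)
  lo <- -40; hi <- 40
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    prev <- mean(stats::plogis(mid + lp))
    if (abs(prev - target_prevalence) <= tol && (hi - lo) < 1e-6)
      return(mid)
    if (prev < target_prevalence) lo <- mid else hi <- mid
  }
  prev <- mean(stats::plogis(mid + lp))
  if (abs(prev - target_prevalence) > tol)
    stop("intercept calibration failed to converge")
  mid
}

#' Assign treatment from the logistic selection model
#'
#' One Bernoulli draw per subject with probability
#' `plogis(intercept + X %*% coef)`.
#'
#' @param X Covariate matrix from [generate_covariates()].
#' @param model A calibrated [treatment_model()].
#' @return Integer vector of 0/1 treatment indicators.
#' @export
assign_treatment <- function(X, model) {
  if (!is.finite(model$intercept))
    stop("treatment model intercept must be finite; calibrate it first")
  p <- stats::plogis(model$intercept + .lp(X, model$coef))
  stats::rbinom(nrow(X), 1L, p)
}

#' Draw treatment-initiation times for treated subjects
#'
#' Used in the time-dependent exposure setting only: subjects assigned to
#' treatment receive a Weibull waiting time; untreated subjects get `NA`.
#'
#' @param treated 0/1 treatment-assignment vector.
#' @param model A [treatment_time_model()].
#' @return Numeric vector of times (days), `NA` where untreated.
#' @export
draw_treatment_times <- function(treated, model = treatment_time_model()) {
  out <- rep(NA_real_, length(treated))
  idx <- treated == 1L
  out[idx] <- stats::rweibull(sum(idx), shape = model$shape,
                              scale = model$scale)
  out
}

## Invert a Weibull cumulative hazard H(t) = rate * exp(lp) * t^shape at the
## exponential deviate e:  T = (e / (rate * exp(lp)))^(1/shape).
.invert_chaz <- function(e, lp, shape, rate) {
  (e / (rate * exp(lp)))^(1 / shape)
}

#' Simulate event times under fixed-at-baseline exposure
#'
#' Event times are generated by inverting the subject-specific cumulative
#' hazard \eqn{H(t) = \lambda t^{\nu} e^{LP}} at a unit-rate exponential
#' deviate, where LP is the covariate linear predictor plus
#' \eqn{\beta_{treat} z}.
#'
#' @param X Covariate matrix.
#' @param treated 0/1 exposure vector.
#' @param model An [outcome_model()].
#' @param e Optional unit-exponential deviates (one per subject); drawn from
#'   the current RNG stream when omitted. Exposed for distributional
#'   identity checks.
#' @return Positive event times (days).
#' @export
simulate_event_times_fixed <- function(X, treated, model, e = NULL) {
  lp <- .lp(X, model$coef) + model$beta_treat * treated
  if (is.null(e)) e <- stats::rexp(nrow(X))
  .invert_chaz(e, lp, model$shape, model$rate)
}

#' Simulate event times under a time-dependent exposure
#'
#' The hazard is \eqn{\lambda \nu t^{\nu-1} e^{LP_0}} before the subject's
#' treatment time \eqn{t_0} and is multiplied by \eqn{e^{\beta_{treat}}}
#' from \eqn{t_0} onward. The piecewise cumulative hazard
#' \deqn{H(t) = e^{LP_0}\lambda t^{\nu}, \quad t < t_0}
#' \deqn{H(t) = e^{LP_0}\{\lambda t_0^{\nu} +
#'   e^{\beta_{treat}}(\lambda t^{\nu} - \lambda t_0^{\nu})\}, \quad t \ge t_0}
#' is inverted at a unit-exponential deviate. Subjects with `treated == 0`
#' or missing `treatment_time` follow the untreated hazard throughout.
#'
#' @param X Covariate matrix.
#' @param treated 0/1 treatment-assignment vector.
#' @param treatment_time Treatment-initiation times (days, `NA` if never).
#' @param model An [outcome_model()].
#' @param e Optional unit-exponential deviates, as in
#'   [simulate_event_times_fixed()].
#' @return Positive event times (days).
#' @export
simulate_event_times_timedep <- function(X, treated, treatment_time, model,
                                         e = NULL) {
  lp0 <- .lp(X, model$coef)
  if (is.null(e)) e <- stats::rexp(nrow(X))
  tt <- .invert_chaz(e, lp0, model$shape, model$rate)
  idx <- which(treated == 1L & is.finite(treatment_time))
  if (length(idx)) {
    t0 <- treatment_time[idx]
    h0 <- model$rate * t0^model$shape          # baseline cum. hazard at t0
    thresh <- exp(lp0[idx]) * h0               # H(t0) per subject
    late <- e[idx] > thresh                    # event falls after t0
    if (any(late)) {
      j <- idx[late]
      chaz <- h0[late] +
        (e[j] * exp(-lp0[j]) - h0[late]) * exp(-model$beta_treat)
      tt[j] <- (chaz / model$rate)^(1 / model$shape)
    }
  }
  tt
}

#' Simulate event times and causes under two competing events
#'
#' Both event types share the cause-specific hazard of the fixed-exposure
#' model, so the all-cause hazard is doubled: times are drawn by inverting
#' the cumulative hazard with rate \eqn{2\lambda}, and the event type is
#' then assigned by an independent fair coin.
#'
#' @inheritParams simulate_event_times_fixed
#' @return A list with components `time` (positive days) and `cause`
#'   (character, `"primary"` or `"competing"`).
#' @export
simulate_event_times_competing <- function(X, treated, model, e = NULL) {
  lp <- .lp(X, model$coef) + model$beta_treat * treated
  if (is.null(e)) e <- stats::rexp(nrow(X))
  tt <- .invert_chaz(e, lp, model$shape, 2 * model$rate)
  cause <- ifelse(stats::rbinom(nrow(X), 1L, 0.5) == 1L,
                  "primary", "competing")
  list(time = tt, cause = cause)
}

#' Apply Type II censoring at a fixed event fraction
#'
#' The `k = floor(event_fraction * n)` subjects with the smallest latent
#' event times experience events at their own times; all remaining subjects
#' are censored at the k-th smallest event time. Ties at the threshold are
#' broken by latent-time order then by subject index, so the realised event
#' count is always exactly `k`.
#'
#' @param latent_times Latent (uncensored) event times.
#' @param event_fraction Fraction of subjects observed to have an event;
#'   must give `k >= 1`.
#' @return A data.frame with columns `observed_time` and `event` (0/1).
#' @export
apply_type2_censoring <- function(latent_times, event_fraction) {
  n <- length(latent_times)
  if (!is.finite(event_fraction) || event_fraction <= 0 || event_fraction > 1)
    stop("'event_fraction' must lie in (0, 1]")
  k <- floor(event_fraction * n)
  if (k < 1)
    stop("'event_fraction' too small: no events would be observed")
  ord <- order(latent_times)                  # stable: ties by index
  event <- logical(n)
  event[ord[seq_len(k)]] <- TRUE
  threshold <- latent_times[ord[k]]
  data.frame(observed_time = ifelse(event, latent_times, threshold),
             event = as.integer(event))
}

#' Define one simulation scenario
#'
#' A scenario is one cell of the factorial design: the exposure/outcome
#' setting, the true treatment hazard ratio, the marginal treatment
#' prevalence, and the fraction of subjects with an observed (primary)
#' event. In setting `"C"` the primary-event fraction refers to the event
#' of interest; censoring operates on the any-event fraction, which is
#' twice as large because the two competing event types are equally likely.
#'
#' @param setting `"A"` (fixed exposure), `"B"` (time-dependent exposure) or
#'   `"C"` (competing risks).
#' @param hazard_ratio True treatment hazard ratio (> 0).
#' @param prevalence Marginal treatment prevalence, in (0, 1).
#' @param event_fraction Fraction of subjects with an observed primary
#'   event, in (0, 0.5].
#' @param n_subjects Cohort size per replicate.
#' @return An object of class `ncc_scenario`.
#' @export
make_scenario <- function(setting = c("A", "B", "C"), hazard_ratio,
                          prevalence, event_fraction, n_subjects = 5000L) {
  setting <- match.arg(setting)
  stopifnot(hazard_ratio > 0, prevalence > 0, prevalence < 1,
            event_fraction > 0, event_fraction <= 0.5, n_subjects >= 2)
  structure(
    list(setting = setting, hazard_ratio = hazard_ratio,
         prevalence = prevalence, event_fraction = event_fraction,
         n_subjects = as.integer(n_subjects)),
    class = "ncc_scenario")
}

#' @export
print.ncc_scenario <- function(x, ...) {
  cat(sprintf(
    "scenario: setting %s, HR %.2f, prevalence %.2f, event fraction %.2f, n %d\n",
    x$setting, x$hazard_ratio, x$prevalence, x$event_fraction, x$n_subjects))
  invisible(x)
}

#' Simulate one cohort for a scenario
#'
#' Generates covariates, assigns treatment from the calibrated logistic
#' model, draws event times from the setting-appropriate Cox-Weibull
#' process, and applies Type II censoring. In setting B, subjects whose
#' latent event precedes their drawn treatment time are recorded as never
#' treated (the treatment was never received during follow-up). In setting
#' C, censoring is applied at the any-event fraction (twice the scenario's
#' primary-event fraction) and the cause label is retained only for
#' observed events.
#'
#' @param scenario An [make_scenario()] object.
#' @param intercept Calibrated treatment-model intercept (see
#'   [calibrate_treatment_intercept()]).
#' @param tx_time_model Waiting-time model for setting B.
#' @return A data.frame of class `ncc_cohort`, one row per subject, with
#'   columns `id`, `x1`..`x6`, `treated`, `treatment_time`, `latent_time`,
#'   `observed_time`, `event`, `cause`; the scenario is attached as
#'   attribute `"scenario"`.
#' @export
simulate_cohort <- function(scenario, intercept,
                            tx_time_model = treatment_time_model()) {
  stopifnot(inherits(scenario, "ncc_scenario"))
  n <- scenario$n_subjects
  X <- generate_covariates(n)
  tm <- treatment_model(intercept = intercept)
  om <- outcome_model(scenario$hazard_ratio)
  z <- assign_treatment(X, tm)
  t0 <- rep(NA_real_, n)
  cause <- rep(NA_character_, n)
  if (scenario$setting == "A") {
    latent <- simulate_event_times_fixed(X, z, om)
    any_fraction <- scenario$event_fraction
  } else if (scenario$setting == "B") {
    t0 <- draw_treatment_times(z, tx_time_model)
    latent <- simulate_event_times_timedep(X, z, t0, om)
    never <- z == 1L & is.finite(t0) & latent < t0
    z[never] <- 0L
    t0[never] <- NA_real_
    any_fraction <- scenario$event_fraction
  } else {
    out <- simulate_event_times_competing(X, z, om)
    latent <- out$time
    cause <- out$cause
    any_fraction <- 2 * scenario$event_fraction
  }
  cens <- apply_type2_censoring(latent, any_fraction)
  cause[cens$event == 0L] <- NA_character_
  if (scenario$setting != "C") cause[cens$event == 1L] <- "primary"
  cohort <- data.frame(id = seq_len(n), X, treated = z, treatment_time = t0,
                       latent_time = latent,
                       observed_time = cens$observed_time,
                       event = cens$event, cause = cause)
  class(cohort) <- c("ncc_cohort", "data.frame")
  attr(cohort, "scenario") <- scenario
  cohort
}

#' Write a cohort to a delimited text file
#'
#' One row per subject in the same column layout as [simulate_cohort()].
#'
#' @param cohort An `ncc_cohort`.
#' @param path Output CSV path.
#' @export
export_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
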