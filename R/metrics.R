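#' Bias of replicate estimates
#'
#' Arithmetic mean of the replicate log-scale estimates minus the true
#' log hazard ratio.
#'
#' @param estimates Replicate estimates (log scale).
#' @param theta True parameter (log scale).
#' @return The bias, `mean(estimates) - theta`.
#' @export
compute_bias <- function(estimates, theta) {
  if (length(estimates) == 0L) stop("no estimates supplied")
  mean(estimates) - theta
}

#' Relative bias of replicate estimates, in percent
#'
#' @inheritParams compute_bias
#' @return `100 * (mean(estimates) - theta) / theta`.
#' @export
compute_relative_bias <- function(estimates, theta) {
  if (length(estimates) == 0L) stop("no estimates supplied")
  if (theta == 0) stop("relative bias is undefined at theta = 0")
  100 * (mean(estimates) - theta) / theta
}

#' Mean squared error of replicate estimates
#'
#' @inheritParams compute_bias
#' @return `mean((estimates - theta)^2)`.
#' @export
compute_mse <- function(estimates, theta) {
  if (length(estimates) == 0L) stop("no estimates supplied")
  mean((estimates - theta)^2)
}

#' Normal-theory significance bounds for empirical coverage
#'
#' Bounds outside of which an empirical coverage proportion over `n_reps`
#' replicates differs significantly (two-sided 5% normal-theory test) from
#' the nominal level: `nominal +/- 1.96 * sqrt(nominal * (1 - nominal) /
#' n_reps)`. For 1000 replicates at the 0.95 level these are 0.9365 and
#' 0.9635 (to four decimals).
#'
#' @param n_reps Number of replicates.
#' @param nominal Nominal coverage level.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
coverage_bounds <- function(n_reps, nominal = 0.95) {
  half <- 1.96 * sqrt(nominal * (1 - nominal) / n_reps)
  c(lower = nominal - half, upper = nominal + half)
}

#' Empirical coverage of confidence intervals
#'
#' Fraction of (closed) intervals containing the true value, with a flag
#' when the empirical rate is significantly different from nominal per
#' [coverage_bounds()].
#'
#' @param ci_lower,ci_upper Interval endpoints (log scale).
#' @param theta True parameter (log scale).
#' @param nominal Nominal coverage level.
#' @return List with `coverage` (proportion) and `flagged` (logical).
#' @export
compute_coverage <- function(ci_lower, ci_upper, theta, nominal = 0.95) {
  cov <- mean(ci_lower <= theta & theta <= ci_upper)
  b <- coverage_bounds(length(ci_lower), nominal)
  list(coverage = cov, flagged = cov < b[["lower"]] || cov > b[["upper"]])
}

#' Ratio of mean confidence-interval widths, NCC relative to cohort
#'
#' Widths are taken on the log scale, so the ratio of mean widths equals
#' the ratio of mean standard errors — the relative statistical efficiency
#' of the two designs.
#'
#' @param ncc_widths,cohort_widths CI widths per replicate for each design.
#' @return `mean(ncc_widths) / mean(cohort_widths)`.
#' @export
compute_width_ratio <- function(ncc_widths, cohort_widths) {
  mean(ncc_widths) / mean(cohort_widths)
}

#' Per-scenario performance metrics
#'
#' Computes, per design, the mean estimate, bias, relative bias (%), MSE,
#' empirical 95% coverage (with significance flag), and mean CI width from
#' per-replicate fit results. Replicates whose fit did not converge are
#' excluded and counted.
#'
#' @param fits Data.frame of per-replicate FitResults with columns `design`,
#'   `estimate`, `std_error`, `ci_lower`, `ci_upper`, `converged`.
#' @param theta True log hazard ratio.
#' @return Data.frame, one row per design: `design`, `n_used`, `n_failed`,
#'   `mean_estimate`, `bias`, `relative_bias`, `mse`, `coverage`,
#'   `coverage_flagged`, `mean_ci_width`.
#' @export
scenario_metrics <- function(fits, theta) {
  out <- lapply(split(fits, fits$design), function(d) {
    ok <- d[d$converged, , drop = FALSE]
    cov <- compute_coverage(ok$ci_lower, ok$ci_upper, theta)
    data.frame(design = d$design[1L], n_used = nrow(ok),
               n_failed = nrow(d) - nrow(ok),
               mean_estimate = mean(ok$estimate),
               bias = compute_bias(ok$estimate, theta),
               relative_bias = compute_relative_bias(ok$estimate, theta),
               mse = compute_mse(ok$estimate, theta),
               coverage = cov$coverage, coverage_flagged = cov$flagged,
               mean_ci_width = mean(ok$ci_upper - ok$ci_lower))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-scenario setting summary
#'
#' Aggregates per-scenario metrics across a factorial grid: per design, the
#' 25th/50th/75th percentiles (linear interpolation between order
#' statistics) of relative bias, MSE and — for each NCC design — the
#' per-scenario NCC/cohort ratio of mean CI widths, plus the count of
#' scenarios whose empirical coverage is significantly different from
#' nominal.
#'
#' @param metrics Per-scenario metrics stacked over scenarios; must contain
#'   a `scenario_id` column in addition to the [scenario_metrics()] columns.
#' @return Data.frame, one row per design, with quartile columns
#'   `relative_bias_q25/q50/q75`, `mse_q25/q50/q75`,
#'   `width_ratio_q25/q50/q75` (NA for the cohort design) and
#'   `n_coverage_flagged`.
#' @export
summarize_setting <- function(metrics) {
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  cohort_w <- metrics[metrics$design == "cohort",
                      c("scenario_id", "mean_ci_width")]
  out <- lapply(split(metrics, metrics$design), function(d) {
    rb <- qs(d$relative_bias); ms <- qs(d$mse)
    wr <- c(NA_real_, NA_real_, NA_real_)
    if (d$design[1L] != "cohort") {
      ratio <- d$mean_ci_width /
        cohort_w$mean_ci_width[match(d$scenario_id, cohort_w$scenario_id)]
      wr <- qs(ratio)
    }
    data.frame(design = d$design[1L], n_scenarios = nrow(d),
               relative_bias_q25 = rb[1L], relative_bias_q50 = rb[2L],
               relative_bias_q75 = rb[3L],
               mse_q25 = ms[1L], mse_q50 = ms[2L], mse_q75 = ms[3L],
               width_ratio_q25 = wr[1L], width_ratio_q50 = wr[2L],
               width_ratio_q75 = wr[3L],
               n_coverage_flagged = sum(d$coverage_flagged))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
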