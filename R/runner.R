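## Seed derivation: one independent-looking substream per (master seed,
## setting, scenario, replicate), by Horner hashing into the Mersenne
## Twister seed space. Scenario identity is hashed from its content, so a
## scenario's results do not depend on which other scenarios run.
.derive_seed <- function(...) {
  h <- 0
  for (v in as.numeric(c(...)))
    h <- (h * 69069 + v + 1) %% 2147483629
  as.integer(h) + 1L
}

.setting_code <- function(setting) match(setting, c("A", "B", "C"))

.scenario_key <- function(scenario) {
  c(.setting_code(scenario$setting), round(scenario$hazard_ratio * 1000),
    round(scenario$prevalence * 1000), round(scenario$event_fraction * 1000),
    scenario$n_subjects)
}

#' Build the factorial scenario grid for one setting
#'
#' The default grid crosses 2 treatment hazard ratios, 3 treatment
#' prevalences and 3 primary-event fractions into 18 scenarios.
#'
#' @param setting `"A"`, `"B"` or `"C"`.
#' @param hazard_ratios,prevalences,event_fractions Factor levels.
#' @param n_subjects Cohort size per replicate.
#' @return List of [make_scenario()] objects.
#' @export
scenario_grid <- function(setting, hazard_ratios = c(1.25, 2),
                          prevalences = c(0.10, 0.25, 0.50),
                          event_fractions = c(0.05, 0.10, 0.25),
                          n_subjects = 5000L) {
  grid <- expand.grid(hazard_ratio = hazard_ratios, prevalence = prevalences,
                      event_fraction = event_fractions)
  lapply(seq_len(nrow(grid)), function(i)
    make_scenario(setting, grid$hazard_ratio[i], grid$prevalence[i],
                  grid$event_fraction[i], n_subjects))
}

#' Calibrate treatment-model intercepts for a set of prevalences
#'
#' One bisection calibration per distinct prevalence, each on its own
#' deterministic substream of the master seed, so every scenario sharing a
#' prevalence reuses the same intercept.
#'
#' @param prevalences Target marginal prevalences.
#' @param seed Master seed.
#' @param calibration_n Calibration sample size.
#' @return Named numeric vector of intercepts (names are the prevalences).
#' @export
calibrate_intercepts <- function(prevalences, seed, calibration_n = 1e6) {
  prevalences <- sort(unique(prevalences))
  tm <- treatment_model()
  out <- vapply(prevalences, function(p) {
    set.seed(.derive_seed(seed, 9090, round(p * 1000)))
    calibrate_treatment_intercept(p, tm, calibration_n = calibration_n)
  }, numeric(1))
  names(out) <- sprintf("%.6g", prevalences)
  out
}

.default_matching <- function(setting) if (setting == "A") c(1L, 5L) else 5L

#' Run one simulation replicate
#'
#' Simulates one cohort for the scenario and analyses it with both designs:
#' the setting-appropriate cohort Cox model (time-invariant, time-dependent
#' or cause-specific) and the nested case-control design at each requested
#' matching ratio. Results are bit-reproducible functions of
#' `(seed, scenario, rep_index)`.
#'
#' @param scenario An [make_scenario()] object.
#' @param rep_index Replicate number (1-based).
#' @param intercept Calibrated treatment-model intercept for the scenario's
#'   prevalence.
#' @param seed Master seed.
#' @param matching Integer vector of NCC matching ratios; default 1:1 and
#'   5:1 in setting A, 5:1 otherwise.
#' @param ties Tie-handling method for the Cox fits.
#' @return Data.frame of FitResults, one row per design, with `design`
#'   labels `"cohort"`, `"ncc_1"`, `"ncc_5"`, ... and a `rep` column.
#' @export
run_replicate <- function(scenario, rep_index, intercept, seed = 1L,
                          matching = .default_matching(scenario$setting),
                          ties = "efron") {
  set.seed(.derive_seed(seed, .scenario_key(scenario), rep_index))
  cohort <- simulate_cohort(scenario, intercept)
  res <- switch(scenario$setting,
    A = fit_cox_fixed(cohort, ties),
    B = fit_cox_timedep(build_counting_process(cohort), ties),
    C = fit_cox_cause_specific(cohort, ties))
  rs <- build_risk_sets(cohort)
  for (m in matching) {
    f <- fit_conditional_logistic(build_matched_sets(cohort, m, rs))
    f$design <- paste0("ncc_", m)
    res <- rbind(res, f)
  }
  res$rep <- rep_index
  res
}

#' Run all replicates of one scenario and summarise them
#'
#' @inheritParams run_replicate
#' @param n_reps Number of replicates.
#' @param keep_fits Retain the per-replicate FitResults in the return value.
#' @return List with `metrics` (see [scenario_metrics()]) and, if requested,
#'   `fits`.
#' @export
run_scenario <- function(scenario, n_reps, intercept = NULL, seed = 1L,
                         matching = .default_matching(scenario$setting),
                         ties = "efron", keep_fits = FALSE) {
  if (is.null(intercept))
    intercept <- unname(calibrate_intercepts(scenario$prevalence, seed))
  fits <- do.call(rbind, lapply(seq_len(n_reps), function(r)
    run_replicate(scenario, r, intercept, seed, matching, ties)))
  metrics <- scenario_metrics(fits, log(scenario$hazard_ratio))
  list(metrics = metrics, fits = if (keep_fits) fits)
}

#' Default factorial configuration
#'
#' @param setting `"A"`, `"B"` or `"C"`.
#' @param preset `"full"` (1000 replicates per scenario) or `"desk"` (250).
#' @param seed Master seed.
#' @return Configuration list for [run_factorial()].
#' @export
default_config <- function(setting = "A", preset = c("desk", "full"),
                           seed = 1L) {
  preset <- match.arg(preset)
  list(setting = setting, hazard_ratios = c(1.25, 2),
       prevalences = c(0.10, 0.25, 0.50),
       event_fractions = c(0.05, 0.10, 0.25), n_subjects = 5000L,
       n_reps = if (preset == "full") 1000L else 250L,
       matching = .default_matching(setting), seed = as.integer(seed),
       calibration_n = 1e6)
}

#' Read a factorial configuration from YAML or JSON
#'
#' Fields missing from the file fall back to [default_config()] values for
#' the file's `setting`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return Configuration list for [run_factorial()].
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- default_config(setting = cfg$setting %||% "A",
                         seed = cfg$seed %||% 1L)
  utils::modifyList(base, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full factorial experiment for one setting
#'
#' Executes every scenario in the grid, computes per-scenario metrics and
#' the cross-scenario setting summary. Scenarios where more than 5% of
#' replicate fits failed for some design trigger a warning.
#'
#' @param config Configuration list, e.g. from [default_config()] or
#'   [read_config()].
#' @param keep_fits Retain all per-replicate FitResults.
#' @param verbose Print per-scenario progress lines.
#' @return List with `scenario_metrics` (per-scenario, with scenario factor
#'   columns), `setting_summary` (see [summarize_setting()]), `scenarios`
#'   (the grid) and optionally `fits`.
#' @export
run_factorial <- function(config = default_config(), keep_fits = FALSE,
                          verbose = FALSE) {
  scens <- scenario_grid(config$setting, config$hazard_ratios,
                         config$prevalences, config$event_fractions,
                         config$n_subjects)
  intercepts <- calibrate_intercepts(config$prevalences, config$seed,
                                     config$calibration_n)
  all_metrics <- vector("list", length(scens))
  all_fits <- if (keep_fits) vector("list", length(scens))
  for (i in seq_along(scens)) {
    sc <- scens[[i]]
    res <- run_scenario(sc, config$n_reps,
                        intercept = unname(intercepts[sprintf("%.6g",
                                                              sc$prevalence)]),
                        seed = config$seed, matching = config$matching,
                        keep_fits = keep_fits)
    m <- res$metrics
    m <- cbind(scenario_id = i, setting = sc$setting,
               hazard_ratio = sc$hazard_ratio, prevalence = sc$prevalence,
               event_fraction = sc$event_fraction, m)
    if (any(m$n_failed > 0.05 * (m$n_used + m$n_failed)))
      warning(sprintf("scenario %d: more than 5%% of replicate fits failed",
                      i))
    all_metrics[[i]] <- m
    if (keep_fits)
      all_fits[[i]] <- cbind(scenario_id = i, res$fits)
    if (verbose)
      message(sprintf("scenario %d/%d done (HR %.2f, prev %.2f, events %.2f)",
                      i, length(scens), sc$hazard_ratio, sc$prevalence,
                      sc$event_fraction))
  }
  metrics <- do.call(rbind, all_metrics)
  list(scenario_metrics = metrics,
       setting_summary = summarize_setting(metrics),
       scenarios = scens,
       fits = if (keep_fits) do.call(rbind, all_fits))
}
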