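#!/usr/bin/env Rscript

# Thin command-line front end over the nccsim package.
#
#   nccsim simulate  --setting A --seed 1 --out-dir out   one cohort to CSV
#   nccsim run       --setting B --reps 250 --seed 1 --out-dir out
#                                                         factorial experiment
#   nccsim run       --config cfg.yaml --out-dir out
#   nccsim summarize --fits out/fits.csv --truth 0.6931 --out-dir out
#
# `run` writes fits.csv (per replicate), scenario_metrics.csv and
# setting_summary.csv under --out-dir.

suppressMessages({
  library(optparse)
  library(nccsim)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !args[1] %in% c("simulate", "run", "summarize")) {
  stop("usage: nccsim <simulate|run|summarize> [options]", call. = FALSE)
}
cmd <- args[1]

parser <- OptionParser(option_list = list(
  make_option("--setting", type = "character", default = "A"),
  make_option("--reps", type = "integer", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--matching", type = "character", default = NULL,
              help = "comma-separated matching ratios, e.g. 1,5"),
  make_option("--preset", type = "character", default = "desk"),
  make_option("--config", type = "character", default = NULL),
  make_option("--hazard-ratio", type = "double", default = 2),
  make_option("--prevalence", type = "double", default = 0.25),
  make_option("--event-fraction", type = "double", default = 0.10),
  make_option("--n-subjects", type = "integer", default = 5000L),
  make_option("--fits", type = "character", default = NULL),
  make_option("--truth", type = "double", default = NULL,
              help = "true log hazard ratio for summarize"),
  make_option("--out-dir", type = "character", default = "nccsim-out")
))
opts <- parse_args(parser, args = args[-1])
dir.create(opts$`out-dir`, showWarnings = FALSE, recursive = TRUE)

if (cmd == "simulate") {
  sc <- make_scenario(opts$setting, opts$`hazard-ratio`, opts$prevalence,
                      opts$`event-fraction`, opts$`n-subjects`)
  b0 <- unname(calibrate_intercepts(sc$prevalence, opts$seed))
  set.seed(opts$seed)
  cohort <- simulate_cohort(sc, b0)
  path <- file.path(opts$`out-dir`, "cohort.csv")
  export_cohort(cohort, path)
  if (opts$setting == "B") {
    cp_path <- file.path(opts$`out-dir`, "counting_process.csv")
    write.csv(build_counting_process(cohort), cp_path, row.names = FALSE)
    message("wrote ", cp_path)
  }
  message("wrote ", path)
} else if (cmd == "run") {
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else
    default_config(opts$setting, preset = opts$preset, seed = opts$seed)
  if (!is.null(opts$reps)) cfg$n_reps <- opts$reps
  if (!is.null(opts$matching))
    cfg$matching <- as.integer(strsplit(opts$matching, ",")[[1]])
  log_path <- file.path(opts$`out-dir`, "run.log")
  out <- withCallingHandlers(
    run_factorial(cfg, keep_fits = TRUE, verbose = TRUE),
    message = function(m) {
      cat(conditionMessage(m), file = log_path, append = TRUE)
      invokeRestart("muffleMessage")
    })
  write.csv(out$fits, file.path(opts$`out-dir`, "fits.csv"),
            row.names = FALSE)
  write.csv(out$scenario_metrics,
            file.path(opts$`out-dir`, "scenario_metrics.csv"),
            row.names = FALSE)
  write.csv(out$setting_summary,
            file.path(opts$`out-dir`, "setting_summary.csv"),
            row.names = FALSE)
  message("results written under ", opts$`out-dir`)
} else {
  if (is.null(opts$fits) || is.null(opts$truth))
    stop("summarize needs --fits and --truth", call. = FALSE)
  fits <- read.csv(opts$fits)
  metrics <- do.call(rbind, lapply(split(fits, fits$scenario_id), function(d)
    cbind(scenario_id = d$scenario_id[1], scenario_metrics(d, opts$truth))))
  write.csv(metrics, file.path(opts$`out-dir`, "scenario_metrics.csv"),
            row.names = FALSE)
  message("results written under ", opts$`out-dir`)
}
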