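# nccsim

Monte Carlo comparison of the **cohort design** (Cox proportional hazards
regression on the full cohort) with the **nested case–control (NCC)
design** (incidence-density sampling of controls followed by conditional
logistic regression) for estimating treatment effects on time-to-event
outcomes, as in pharmacoepidemiological studies built on administrative
databases.

Both designs start from the same well-defined cohort, so the question is
statistical, not logistical: how much bias and precision does the NCC
design trade away by analysing each case against a handful of sampled
controls instead of the full risk set, and how does that trade-off change
when the exposure varies over time or a competing event is present?

## The model

Cohorts of *n* = 5000 subjects carry six baseline covariates
(`x1`–`x3` ~ Bernoulli(0.5), `x4`–`x6` ~ N(0,1)). Treatment is
confounded: it is assigned by a logistic model with odds ratios
1.10/1.50/2 on covariate pairs, with the intercept calibrated by
bisection to a target marginal prevalence. Event times follow a Cox
model

  h(t | x, z) = h₀(t) · exp(α′x + β z),   H₀(t) = λ t^ν,  ν = 0.45, λ = 0.01,

with covariate hazard ratios 1.25/2/3 and treatment hazard ratio
e^β ∈ {1.25, 2}; times are drawn by inverting the cumulative hazard at a
unit-exponential deviate. Three settings:

* **A** — treatment fixed at baseline;
* **B** — treatment begins after a Weibull(0.25, 433.2097 days) waiting
  time (median 100 days), with the hazard multiplied by e^β from then on
  (piecewise cumulative-hazard inversion);
* **C** — two competing event types with equal cause-specific hazards
  (all-cause hazard doubled, type assigned by a fair coin).

Type II censoring fixes the number of observed events at
⌊q·n⌋ exactly, q ∈ {0.05, 0.10, 0.25} (any-event fractions
0.10/0.20/0.50 in setting C). Each replicate is analysed with the
setting-appropriate Cox model (time-invariant, counting-process
time-dependent, or cause-specific) and with the NCC design (1:1 and 5:1
matching in setting A, 5:1 otherwise), and the designs are compared by
bias, relative bias, MSE, 95% CI coverage and the NCC/cohort ratio of
mean CI widths across an 18-scenario factorial grid
(2 hazard ratios × 3 prevalences × 3 event fractions) per setting.

## Worked example

One factorial cell of setting A (HR = 2, prevalence 0.25, event fraction
0.10) at 250 replicates of n = 5000:

```r
library(nccsim)

cfg <- default_config("A", preset = "desk", seed = 1)
cfg$hazard_ratios <- 2
cfg$prevalences <- 0.25
cfg$event_fractions <- 0.10
out <- run_factorial(cfg)
out$scenario_metrics[, c("design", "relative_bias", "mse", "coverage",
                         "mean_ci_width")]
#>   design relative_bias     mse coverage mean_ci_width
#> 1 cohort        -0.165 0.00968    0.940         0.373
#> 2  ncc_1         2.903 0.05172    0.948         0.844
#> 3  ncc_5         0.586 0.01431    0.972         0.502
```

Reading this: all three estimators centre near the true log hazard ratio
(relative bias is in percent of log 2), coverage is compatible with the
nominal 95%, but the cohort design's intervals are much narrower — the
5:1 NCC intervals are 0.502/0.373 ≈ 1.35 times as wide (so its MSE is
about 1.5× larger), and 1:1 matching is far costlier still (width ratio
≈ 2.3, MSE ≈ 5×). `run_factorial()` over the default grid aggregates
these into cross-scenario medians and quartiles per design
(`setting_summary`).

A command-line wrapper is available for shell use:

```sh
Rscript scripts/nccsim run --setting A --reps 250 --seed 1 --out-dir out
```

writes `fits.csv`, `scenario_metrics.csv` and `setting_summary.csv`.

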