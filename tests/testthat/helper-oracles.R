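# Hand-built fixtures and independent oracles used across the test files.

# Assemble an ncc_cohort directly from its columns, bypassing the
# generator, for definitional tests of risk sets and analyses.
mk_cohort <- function(observed_time, event, treated,
                      setting = "A", treatment_time = NULL, cause = NULL,
                      X = NULL, hazard_ratio = 2, prevalence = 0.25,
                      event_fraction = 0.25, latent_time = observed_time) {
  n <- length(observed_time)
  if (is.null(X))
    X <- matrix(0, n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  if (is.null(treatment_time)) treatment_time <- rep(NA_real_, n)
  if (is.null(cause))
    cause <- ifelse(event == 1L, "primary", NA_character_)
  cohort <- data.frame(id = seq_len(n), X, treated = as.integer(treated),
                       treatment_time = treatment_time,
                       latent_time = latent_time,
                       observed_time = observed_time,
                       event = as.integer(event), cause = cause)
  class(cohort) <- c("ncc_cohort", "data.frame")
  attr(cohort, "scenario") <- make_scenario(setting, hazard_ratio,
                                            prevalence, event_fraction, n)
  cohort
}

# Brute-force Cox partial log-likelihood (Breslow) by explicit risk-set
# enumeration over counting-process rows: at each event time t the risk
# set is every interval with start < t <= stop.
bf_cox_loglik <- function(beta, X, start, stop, event) {
  lp <- drop(X %*% beta)
  ll <- 0
  for (i in which(event == 1L)) {
    t <- stop[i]
    at_risk <- start < t & t <= stop
    ll <- ll + lp[i] - log(sum(exp(lp[at_risk])))
  }
  ll
}

# Maximise the brute-force partial likelihood numerically.
bf_cox_mle <- function(X, start, stop, event) {
  p <- ncol(X)
  opt <- stats::optim(rep(0, p),
                      function(b) -bf_cox_loglik(b, X, start, stop, event),
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  list(coef = opt$par, loglik = -opt$value)
}
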