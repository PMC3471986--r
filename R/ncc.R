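#' Build incidence-density risk sets
#'
#' For each case (subject with an observed primary event) the risk set is
#' the set of subjects who, at the case's event time (the index date), had
#' not yet experienced the event of interest and were not yet censored:
#' everyone whose follow-up for the primary event extends to the index
#' date, excluding the case itself. Later cases are eligible as controls
#' for earlier cases; ties with the index date count as still eligible.
#'
#' In the competing-risks setting the treatment of subjects with a
#' competing event is governed by `competing_exit`. The default,
#' `"retain"`, keeps them eligible as controls for later index dates —
#' they have not experienced the event of interest, which is how the
#' sampled design defines its control pool. The alternative, `"remove"`,
#' drops them at their competing-event time, so that risk sets coincide
#' with those of the cause-specific partial likelihood.
#'
#' Membership is stored implicitly: subjects are sorted by their
#' eligibility-exit time and each risk set is a suffix of that ordering
#' minus the case. Use [risk_set_members()] to materialise one set.
#'
#' @param cohort An `ncc_cohort`.
#' @param competing_exit Eligibility rule for competing-event subjects
#'   (setting C only): `"retain"` or `"remove"`.
#' @return An object of class `ncc_risk_sets` with one entry per case, in
#'   index-date order: `case_id`, `index_date`, `n_at_risk` (potential
#'   controls, case excluded).
#' @export
build_risk_sets <- function(cohort, competing_exit = c("retain", "remove")) {
  competing_exit <- match.arg(competing_exit)
  scen <- attr(cohort, "scenario")
  setting_c <- !is.null(scen) && scen$setting == "C"
  primary <- cohort$event == 1L
  if (setting_c)
    primary <- primary & !is.na(cohort$cause) & cohort$cause == "primary"
  case_id <- cohort$id[primary]
  index_date <- cohort$observed_time[primary]
  o <- order(index_date, case_id)
  case_id <- case_id[o]; index_date <- index_date[o]

  exit_time <- cohort$observed_time
  if (setting_c && competing_exit == "retain") {
    ## competing events do not end eligibility: such subjects stay in the
    ## control pool until the end of the study (the censoring threshold)
    competing <- cohort$event == 1L & !is.na(cohort$cause) &
      cohort$cause == "competing"
    exit_time[competing] <- max(cohort$observed_time)
  }
  ord <- order(exit_time, cohort$id)
  sorted_ids <- cohort$id[ord]
  sorted_times <- exit_time[ord]
  n <- length(sorted_ids)
  ## first sorted position with exit time >= index date
  first_pos <- findInterval(index_date, sorted_times, left.open = TRUE) + 1L
  structure(
    list(case_id = case_id, index_date = index_date, first_pos = first_pos,
         case_pos = match(case_id, sorted_ids),
         n_at_risk = n - first_pos,           # suffix size minus the case
         sorted_ids = sorted_ids, n = n),
    class = "ncc_risk_sets")
}

#' @export
print.ncc_risk_sets <- function(x, ...) {
  cat(sprintf("%d risk sets; at-risk sizes %d-%d\n", length(x$case_id),
              if (length(x$n_at_risk)) min(x$n_at_risk) else 0L,
              if (length(x$n_at_risk)) max(x$n_at_risk) else 0L))
  invisible(x)
}

#' Materialise the members of one risk set
#'
#' @param risk_sets An `ncc_risk_sets` object.
#' @param i Case number (position in index-date order).
#' @return Integer vector of member subject ids (the case's potential
#'   controls; the case itself is excluded).
#' @export
risk_set_members <- function(risk_sets, i) {
  pos <- seq.int(risk_sets$first_pos[i], risk_sets$n)
  pos <- pos[pos != risk_sets$case_pos[i]]
  risk_sets$sorted_ids[pos]
}

## Uniform sample of min(m, k) distinct integers from 1..k. Rejection
## sampling beats sample.int's set-up cost when the pool is much larger
## than the draw; both routes are uniform without replacement.
.sample_wor <- function(k, m) {
  if (m >= k) return(seq_len(k))
  if (k > 50L * m) {
    repeat {
      j <- unique(floor(stats::runif(m) * k) + 1L)
      if (length(j) == m) return(j)
    }
  }
  sample.int(k, m)
}

#' Sample controls from one risk set
#'
#' Simple random sampling without replacement within the risk set; at most
#' `m` controls, fewer when the risk set is smaller. Sampling is
#' independent across cases, so a subject may serve as a control for
#' several cases and a sampled control may itself be a later case.
#'
#' @inheritParams risk_set_members
#' @param m Matching ratio (controls per case).
#' @return Integer vector of control subject ids (possibly empty).
#' @export
sample_controls <- function(risk_sets, i, m) {
  k <- risk_sets$n_at_risk[i]
  if (k < 1L) return(integer(0))
  j <- .sample_wor(k, m)
  ## map positions within the suffix, skipping over the case's own slot
  rel_case <- risk_sets$case_pos[i] - risk_sets$first_pos[i] + 1L
  j <- j + (j >= rel_case)
  risk_sets$sorted_ids[risk_sets$first_pos[i] + j - 1L]
}

#' Exposure status at an index date
#'
#' With exposure fixed at baseline (settings A and C) this is the baseline
#' treatment flag regardless of the index date. With a time-dependent
#' exposure (setting B) a subject counts as exposed only if treated
#' strictly before the index date; there the index date must not exceed
#' the subject's observed time, since exposure beyond follow-up is not
#' ascertainable.
#'
#' @param cohort An `ncc_cohort`.
#' @param ids Subject ids.
#' @param index_date Index date (days); recycled against `ids`.
#' @return Integer 0/1 exposure indicators.
#' @export
determine_exposure <- function(cohort, ids, index_date) {
  scen <- attr(cohort, "scenario")
  if (!is.null(scen) && scen$setting == "B") {
    if (any(index_date > cohort$observed_time[ids] + 1e-9))
      stop("index date falls after a subject's observed time")
    tt <- cohort$treatment_time[ids]
    as.integer(cohort$treated[ids] == 1L & is.finite(tt) & tt < index_date)
  } else {
    as.integer(cohort$treated[ids])
  }
}

#' Draw all matched case-control sets for a cohort
#'
#' Builds the risk sets, samples `m` controls per case by incidence-density
#' sampling, assigns every member the case's index date, and evaluates
#' exposure strictly before the index date. Cases with an empty risk set
#' contribute no matched set and are counted in the `"n_unmatched"`
#' attribute.
#'
#' @param cohort An `ncc_cohort`.
#' @param m Matching ratio (e.g. 1 or 5).
#' @param risk_sets Optionally, precomputed [build_risk_sets()] output.
#' @return A long-format data.frame, one row per matched-set member:
#'   `set_id`, `subject_id`, `case` (1 for the case, 0 for controls),
#'   `index_date`, `exposure`, `x1`..`x6`.
#' @export
build_matched_sets <- function(cohort, m, risk_sets = NULL) {
  stopifnot(m >= 1)
  if (is.null(risk_sets)) risk_sets <- build_risk_sets(cohort)
  nc <- length(risk_sets$case_id)
  keep <- which(risk_sets$n_at_risk >= 1L)
  case_id <- risk_sets$case_id; first_pos <- risk_sets$first_pos
  case_pos <- risk_sets$case_pos; n_at_risk <- risk_sets$n_at_risk
  sorted_ids <- risk_sets$sorted_ids
  ids <- vector("list", length(keep))
  for (s in seq_along(keep)) {
    i <- keep[s]
    j <- .sample_wor(n_at_risk[i], m)
    j <- j + (j >= case_pos[i] - first_pos[i] + 1L)
    ids[[s]] <- c(case_id[i], sorted_ids[first_pos[i] + j - 1L])
  }
  sizes <- lengths(ids)
  subject_id <- unlist(ids, use.names = FALSE)
  set_id <- rep.int(seq_along(keep), sizes)
  index_date <- rep.int(risk_sets$index_date[keep], sizes)
  case <- integer(length(subject_id))
  case[cumsum(c(1L, sizes[-length(sizes)]))] <- 1L
  out <- data.frame(set_id = set_id, subject_id = subject_id, case = case,
                    index_date = index_date,
                    exposure = determine_exposure(cohort, subject_id,
                                                  index_date))
  out <- cbind(out, as.matrix(cohort[subject_id, .covariate_cols]))
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- nc - length(keep)
  out
}

#' Nested case-control analysis: conditional logistic regression
#'
#' Estimates the exposure log-odds ratio from the matched sets by the
#' stratified conditional likelihood, adjusting for the six baseline
#' covariates. With one case per set this likelihood coincides with the
#' Cox partial likelihood over the sampled risk sets, so the fit is
#' performed through the equivalent stratified Cox model.
#'
#' @param sets Matched sets from [build_matched_sets()].
#' @param ties Partial-likelihood tie method; with a single case per set
#'   Breslow, Efron and the exact conditional likelihood coincide.
#' @return One-row FitResult data.frame (`design = "ncc"`): `estimate` is
#'   the exposure log-odds ratio.
#' @export
fit_conditional_logistic <- function(sets, ties = "breslow") {
  if (nrow(sets) == 0L) return(.fit_result(NULL, "ncc"))
  Xmat <- cbind(exposure = sets$exposure,
                as.matrix(sets[, .covariate_cols]))
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(Xmat,
                          survival::Surv(rep(1, nrow(sets)), sets$case),
                          strata = sets$set_id, offset = NULL, init = NULL,
                          control = survival::coxph.control(),
                          weights = NULL, method = ties, rownames = NULL)),
    error = function(e) NULL)
  .fit_result(fit, "ncc")
}
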