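#' Cohort column holding a task's standardised decision parameter
#'
#' @param task One of the four task labels from [vbdm_tasks()].
#' @return The column name.
#' @export
task_zcol <- function(task) {
  cols <- c(delay = "z_logk_delay", prob_gain = "z_logk_pgain",
            prob_loss = "z_logk_ploss", loss_aversion = "z_loglambda")
  if (!task %in% names(cols)) stop("unknown task: ", task)
  unname(cols[[task]])
}

vbdm_covariates <- function() c("age", "female", "iq", "income_low", "abitur")

#' Bayesian group-difference analysis for one task
#'
#' Regresses the standardised decision parameter on dummy-coded group
#' membership (control group as reference) plus the demographic covariates,
#' with the task's informative prior on both group coefficients and vague
#' priors elsewhere. Returns directional results for the SUD-control and
#' ND-control coefficients and the posterior SUD-vs-ND contrast (the
#' percentage of paired posterior draws with SUD-control above ND-control).
#'
#' @param cohort A `vbdm_cohort`.
#' @param task Task label.
#' @param priors Priors per task, as from [default_priors("group_diff")].
#' @param mcmc A `vbdm_mcmc_config`.
#' @return List: `task`, `direction`, `fit`, `sud`, `nd` (directional
#'   results), `likelihood_sud`, `likelihood_nd` (OLS summaries),
#'   `contrast_pct_above` (percent of draws with SUD coefficient above ND).
#' @export
fit_group_difference <- function(cohort, task,
                                 priors = default_priors("group_diff"),
                                 mcmc = mcmc_config()) {
  spec <- priors[[task]]
  f <- stats::reformulate(c("group", vbdm_covariates()),
                          response = task_zcol(task))
  data <- cohort[stats::complete.cases(cohort[, c(task_zcol(task), "group",
                                                  vbdm_covariates())]), ]
  fit <- fit_bayes_lm(f, data,
                      priors = list(groupSUD = spec$prior,
                                    groupND = spec$prior),
                      mcmc = mcmc)
  list(
    task = task, direction = spec$direction, fit = fit,
    sud = directional_result(fit, "groupSUD", spec$direction),
    nd = directional_result(fit, "groupND", spec$direction),
    likelihood_sud = fit_likelihood_lm(f, data, "groupSUD"),
    likelihood_nd = fit_likelihood_lm(f, data, "groupND"),
    contrast_pct_above = group_contrast(fit$draws[, "groupSUD"],
                                        fit$draws[, "groupND"])
  )
}

#' Assemble the modelling frame for one prediction analysis
#'
#' Applies attrition masking, builds the standardised one-year change score
#' for the requested outcome (criteria sums directly; QFI outcomes through
#' the long-format two-stage standardisation), and merges the predictor and
#' covariates. Predictor and baseline are re-standardised within the
#' analysis sample so coefficients are standardised.
#'
#' @param cohort A `vbdm_cohort`.
#' @param task Task label (predictor).
#' @param outcome One of `"sud_criteria"`, `"nd_criteria"`, `"qfi_sud"`,
#'   `"qfi_nd"`.
#' @return Data frame with columns `change_z`, `pred`, `baseline`, `group`,
#'   and the covariates.
#' @export
prediction_data <- function(cohort, task, outcome) {
  masked <- attrit(cohort)
  if (outcome %in% c("sud_criteria", "nd_criteria")) {
    bl <- paste0(outcome, "_bl"); fu <- paste0(outcome, "_fu")
    chg <- suppressWarnings(build_change_outcome(masked, bl, fu))
  } else {
    cls <- sub("qfi_", "", outcome)
    scores <- class_qfi_scores(severity_long(masked))
    scores <- scores[scores$class == cls, ]
    wide <- stats::reshape(scores[, c("id", "wave", "qfi_z")],
                           idvar = "id", timevar = "wave",
                           direction = "wide")
    names(wide) <- sub("^qfi_z\\.", "", names(wide))
    chg <- suppressWarnings(build_change_outcome(wide, "baseline",
                                                 "follow_up"))
  }
  d <- merge(chg, masked[, c("id", "group", task_zcol(task),
                             vbdm_covariates())], by = "id")
  d$pred <- standardize_long(d[[task_zcol(task)]])
  d$baseline <- standardize_long(d$baseline)
  d
}

#' Bayesian one-year prediction analysis for one task and outcome
#'
#' Regresses the standardised change score on the standardised decision
#' parameter, adjusting for the baseline value of the outcome and the
#' demographic covariates; the informative prediction prior sits on the
#' predictor. With `interaction = TRUE` the model additionally contains
#' group dummies and group-by-predictor interaction terms (control group as
#' reference) carrying the same prior as the predictor, and directional
#' results are returned per interaction coefficient.
#'
#' @param cohort A `vbdm_cohort`.
#' @param task Task label.
#' @param outcome Outcome label, see [prediction_data()].
#' @param priors Priors per task, as from [default_priors("prediction")].
#' @param mcmc A `vbdm_mcmc_config`.
#' @param interaction Include group-by-predictor interaction terms?
#' @return List: `task`, `outcome`, `direction`, `fit`, `predictor`
#'   (directional result), `likelihood` (OLS summary), and with
#'   `interaction = TRUE` also `interaction_sud` / `interaction_nd`.
#' @export
fit_prediction <- function(cohort, task, outcome,
                           priors = default_priors("prediction"),
                           mcmc = mcmc_config(), interaction = FALSE) {
  spec <- priors[[task]]
  d <- prediction_data(cohort, task, outcome)
  rhs <- c("pred", "baseline", vbdm_covariates())
  pr <- list(pred = spec$prior)
  if (interaction) {
    rhs <- c(rhs, "group", "pred:group")
    pr[["pred:groupSUD"]] <- spec$prior
    pr[["pred:groupND"]] <- spec$prior
  }
  f <- stats::reformulate(rhs, response = "change_z")
  fit <- fit_bayes_lm(f, d, priors = pr, mcmc = mcmc)
  out <- list(
    task = task, outcome = outcome, direction = spec$direction, fit = fit,
    predictor = directional_result(fit, "pred", spec$direction),
    likelihood = fit_likelihood_lm(f, d, "pred")
  )
  if (interaction) {
    out$interaction_sud <- directional_result(fit, "pred:groupSUD",
                                              spec$direction)
    out$interaction_nd <- directional_result(fit, "pred:groupND",
                                             spec$direction)
  }
  out
}

#' OLS likelihood coefficient for one prediction analysis
#'
#' The flat-prior (data-only) standardised coefficient of the predictor in
#' the one-year change model — the quantity the cohort generator's `assoc`
#' entries target.
#'
#' @inheritParams fit_prediction
#' @return A `vbdm_normal`.
#' @export
prediction_likelihood <- function(cohort, task, outcome) {
  d <- prediction_data(cohort, task, outcome)
  f <- stats::reformulate(c("pred", "baseline", vbdm_covariates()),
                          response = "change_z")
  fit_likelihood_lm(f, d, "pred")
}

#' OLS likelihood coefficients for one group-difference analysis
#'
#' @param cohort A `vbdm_cohort`.
#' @param task Task label.
#' @return List of `vbdm_normal` summaries: `sud`, `nd`.
#' @export
group_difference_likelihood <- function(cohort, task) {
  f <- stats::reformulate(c("group", vbdm_covariates()),
                          response = task_zcol(task))
  list(sud = fit_likelihood_lm(f, cohort, "groupSUD"),
       nd = fit_likelihood_lm(f, cohort, "groupND"))
}
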