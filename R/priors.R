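#' Default informative priors for the two analysis families
#'
#' Group-difference priors (from an earlier clinical sample): delay
#' discounting N(0.37, var 0.02) with hypothesised direction "greater";
#' probability discounting for gains and for losses each N(-0.16, var 0.02),
#' direction "less"; loss aversion N(-0.44, var 0.02), direction "less".
#' Prediction priors encode a 95% belief that the standardised association
#' lies in \[0, 0.5\] (delay discounting; direction "greater") or
#' \[-0.5, 0\] (other tasks; direction "less"): N(+/-0.25, var 0.016,
#' sd 0.1276). Covariates and the intercept get vague N(0, var 1e4) priors.
#'
#' @param analysis `"group_diff"` or `"prediction"`.
#' @return A named list per task with elements `prior` (`vbdm_normal`) and
#'   `direction`.
#' @export
default_priors <- function(analysis = c("group_diff", "prediction")) {
  analysis <- match.arg(analysis)
  if (analysis == "group_diff") {
    list(
      delay       = list(prior = normal_summary(0.37, sqrt(0.02)),
                         direction = "greater"),
      prob_gain   = list(prior = normal_summary(-0.16, sqrt(0.02)),
                         direction = "less"),
      prob_loss   = list(prior = normal_summary(-0.16, sqrt(0.02)),
                         direction = "less"),
      loss_aversion = list(prior = normal_summary(-0.44, sqrt(0.02)),
                           direction = "less")
    )
  } else {
    sd_pred <- prediction_prior_sd()
    list(
      delay       = list(prior = normal_summary(0.25, sd_pred),
                         direction = "greater"),
      prob_gain   = list(prior = normal_summary(-0.25, sd_pred),
                         direction = "less"),
      prob_loss   = list(prior = normal_summary(-0.25, sd_pred),
                         direction = "less"),
      loss_aversion = list(prior = normal_summary(-0.25, sd_pred),
                           direction = "less")
    )
  }
}

#' Standard deviation of the prediction prior
#'
#' The prediction prior places 95% probability on a standardised association
#' between 0 and 0.5 (a medium effect): a normal with mean 0.25 whose central
#' 95% interval is exactly \[0, 0.5\], i.e. `sd = 0.25 / qnorm(0.975)`
#' (0.12755; variance 0.01627, rounding to 0.016).
#'
#' @return The standard deviation.
#' @export
prediction_prior_sd <- function() {
  0.25 / stats::qnorm(0.975)
}

#' Vague prior used for covariates and the intercept
#'
#' @return A `vbdm_normal` with mean 0 and variance 1e4.
#' @export
vague_prior <- function() normal_summary(0, 100)
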