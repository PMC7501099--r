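#' Normal summary of a regression coefficient
#'
#' The (mean, sd) summary of a prior, likelihood, or posterior distribution
#' for one coefficient — the common currency of the conjugate combination
#' machinery. Either `sd` or a central 95% interval `ci` may be supplied;
#' when both are given they must agree to 1e-6 after inverting the interval.
#'
#' @param mean Coefficient-scale mean.
#' @param sd Standard deviation (> 0), or `NULL` to derive it from `ci`.
#' @param ci Optional `c(lower, upper)` central interval.
#' @param level Interval coverage, default 0.95.
#' @return A `vbdm_normal` list with `mean`, `sd`, `ci`.
#' @export
normal_summary <- function(mean, sd = NULL, ci = NULL, level = 0.95) {
  stopifnot(is.numeric(mean), length(mean) == 1, is.finite(mean))
  if (is.null(sd) && is.null(ci)) stop("supply `sd` or `ci`")
  if (!is.null(ci)) {
    sd_ci <- ci_to_sd(ci[1], ci[2], level)
    if (!is.null(sd) && abs(sd - sd_ci) >= 1e-6) {
      stop("`sd` and `ci` disagree: ", sd, " vs ", sd_ci)
    }
    sd <- if (is.null(sd)) sd_ci else sd
  }
  if (!is.finite(sd) || sd <= 0) stop("`sd` must be positive")
  z <- stats::qnorm((1 + level) / 2)
  structure(
    list(mean = mean, sd = sd, ci = c(mean - z * sd, mean + z * sd)),
    class = "vbdm_normal"
  )
}

#' @export
print.vbdm_normal <- function(x, ...) {
  cat(sprintf("N(mean = %.4f, sd = %.4f)  95%% CI [%.4f, %.4f]\n",
              x$mean, x$sd, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Convert a central normal interval to a standard deviation
#'
#' `sd = (upper - lower) / (2 * z)`, with `z = qnorm((1 + level) / 2)`
#' (1.959964 at 95%). Inverts the printed 95% credibility/confidence
#' intervals of reported summary tables.
#'
#' @param lower,upper Interval bounds (`upper > lower`).
#' @param level Coverage, default 0.95.
#' @return The standard deviation.
#' @export
ci_to_sd <- function(lower, upper, level = 0.95) {
  if (any(upper <= lower)) stop("`upper` must exceed `lower`")
  (upper - lower) / (2 * stats::qnorm((1 + level) / 2))
}

#' Precision-weighted (conjugate) combination of two normal summaries
#'
#' The normal-normal conjugate update with known scale: precisions add and
#' the posterior mean is the precision-weighted average of the prior and
#' likelihood means. Symmetric in its arguments.
#'
#' @param prior,likelihood `vbdm_normal` objects (or anything accepted by
#'   `as_normal()`).
#' @return The posterior `vbdm_normal`.
#' @export
combine_normal_summaries <- function(prior, likelihood) {
  prior <- as_normal(prior)
  likelihood <- as_normal(likelihood)
  w1 <- 1 / prior$sd^2
  w2 <- 1 / likelihood$sd^2
  normal_summary((w1 * prior$mean + w2 * likelihood$mean) / (w1 + w2),
                 sd = sqrt(1 / (w1 + w2)))
}

as_normal <- function(x) {
  if (inherits(x, "vbdm_normal")) return(x)
  if (is.numeric(x) && length(x) == 2) return(normal_summary(x[1], x[2]))
  stop("cannot interpret as a normal summary")
}

#' Directional posterior probability
#'
#' The posterior probability, in percent, that a coefficient lies in the
#' hypothesised direction. For a normal summary this is
#' `100 * pnorm(mean / sd)` for `"greater"` (sign-flipped for `"less"`); for
#' a vector of posterior draws it is 100 times the fraction of draws on the
#' hypothesised side of zero, draws exactly at zero counting half.
#'
#' @param x A `vbdm_normal` or a numeric vector of posterior draws.
#' @param direction `"greater"` or `"less"` (than zero).
#' @return Probability in percent, in \[0, 100\].
#' @export
directional_probability <- function(x, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (inherits(x, "vbdm_normal")) {
    z <- x$mean / x$sd
    if (direction == "less") z <- -z
    return(100 * stats::pnorm(z))
  }
  stopifnot(is.numeric(x), length(x) > 0)
  side <- if (direction == "greater") x > 0 else x < 0
  100 * (sum(side) + 0.5 * sum(x == 0)) / length(x)
}
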