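#' Subjective value of a delayed reward
#'
#' Hyperbolic discounting: `V = A / (1 + k * D)`. The subjective value of a
#' delayed reward declines hyperbolically with the delay `D` (in days) at the
#' individual discounting rate `k`; larger `k` means steeper discounting and
#' more impulsive choice.
#'
#' @param amount Reward magnitude in euros (> 0).
#' @param delay Delay to receipt in days (>= 0).
#' @param k Discounting rate (>= 0), per day.
#' @return Subjective value on the same scale as `amount`.
#' @examples
#' subjective_value_delayed(10, 14, 0.1)   # 10 / (1 + 1.4)
#' @export
subjective_value_delayed <- function(amount, delay, k) {
  stopifnot(is.numeric(amount), is.numeric(delay), is.numeric(k))
  if (any(!is.finite(amount)) || any(amount <= 0)) {
    stop("`amount` must be finite and positive")
  }
  if (any(delay < 0)) stop("`delay` must be non-negative")
  if (any(k < 0)) stop("`k` must be non-negative")
  amount / (1 + k * delay)
}

#' Subjective value of a probabilistic outcome
#'
#' Hyperbolic probability discounting in odds-against form: with
#' `theta = (1 - p) / p`, `V = A / (1 + k * theta)`. For gains, lower `k`
#' means greater risk-seeking; in loss framing `amount` is negative and the
#' value keeps the sign of the amount.
#'
#' @param amount Outcome magnitude in euros (non-zero; negative for losses).
#' @param p Probability of receiving the outcome, in (0, 1].
#' @param k Discounting rate over odds-against (>= 0).
#' @return Subjective value; `|V| <= |amount|`, equal at `p = 1`.
#' @export
subjective_value_probabilistic <- function(amount, p, k) {
  stopifnot(is.numeric(amount), is.numeric(p), is.numeric(k))
  if (any(!is.finite(amount)) || any(amount == 0)) {
    stop("`amount` must be finite and non-zero")
  }
  if (any(p <= 0) || any(p > 1)) stop("`p` must lie in (0, 1]")
  if (any(k < 0)) stop("`k` must be non-negative")
  theta <- (1 - p) / p
  amount / (1 + k * theta)
}

#' Linear utility of a 50/50 mixed gamble
#'
#' `U = 0.5 * gain - 0.5 * lambda * loss`: loss aversion `lambda` is the
#' relative weighting of losses to gains. `U = 0` exactly when
#' `gain = lambda * loss`, the indifference point against rejecting the
#' gamble (utility 0).
#'
#' @param gain,loss Gamble outcomes in euros (both >= 0; `loss` is the
#'   magnitude of the potential loss).
#' @param lam Loss-aversion coefficient (> 0).
#' @return Utility on the euro scale.
#' @export
gamble_utility <- function(gain, loss, lam) {
  stopifnot(is.numeric(gain), is.numeric(loss), is.numeric(lam))
  if (any(gain < 0) || any(loss < 0)) stop("`gain` and `loss` must be >= 0")
  if (any(!is.finite(lam)) || any(lam <= 0)) stop("`lam` must be positive")
  0.5 * gain - 0.5 * lam * loss
}

#' Logistic (softmax) choice probability
#'
#' Probability of choosing option B over option A given their subjective
#' values and a choice-consistency (inverse-temperature) parameter:
#' `P(B) = 1 / (1 + exp(-beta * (value_b - value_a)))`. `beta = 0` is random
#' responding (P = 0.5); large `beta` approaches deterministic
#' value-maximisation.
#'
#' @param value_b,value_a Subjective values of the two options.
#' @param beta Choice consistency (>= 0).
#' @return Probability in (0, 1).
#' @export
choice_probability <- function(value_b, value_a, beta) {
  stopifnot(is.numeric(value_b), is.numeric(value_a), is.numeric(beta))
  if (any(!is.finite(value_b)) || any(!is.finite(value_a))) {
    stop("option values must be finite")
  }
  if (any(beta < 0)) stop("`beta` must be non-negative")
  stats::plogis(beta * (value_b - value_a))
}
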