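#' Discrete joint posterior over a decision parameter and choice consistency
#'
#' The adaptive estimation runs on a fixed grid: candidate values of the
#' task's decision parameter on the log scale (`log k` for discounting tasks,
#' `log lambda` for mixed gambles) crossed with candidate values of
#' `log beta` (choice consistency). The joint mass starts uniform and is
#' re-weighted by Bayes' rule after every trial.
#'
#' Default axes: `log k` on 41 nodes over \[-7, 2\], `log lambda` on 41 nodes
#' over \[-2, 2\], `log beta` on 11 nodes over \[-3, 2\]; these cover
#' reported human ranges.
#'
#' @param param_axis Ordered grid of candidate log-parameter values.
#' @param beta_axis Ordered grid of candidate log-beta values.
#' @param mass Optional matrix of initial mass, `length(param_axis)` x
#'   `length(beta_axis)`; defaults to uniform.
#' @return A `vbdm_grid` object.
#' @export
posterior_grid <- function(param_axis, beta_axis, mass = NULL) {
  stopifnot(length(param_axis) >= 2, length(beta_axis) >= 1,
            !is.unsorted(param_axis), !is.unsorted(beta_axis))
  if (is.null(mass)) {
    mass <- matrix(1, length(param_axis), length(beta_axis))
    mass <- mass / sum(mass)
  }
  stopifnot(nrow(mass) == length(param_axis), ncol(mass) == length(beta_axis))
  if (any(mass < 0)) stop("grid mass must be non-negative")
  mass <- mass / sum(mass)
  structure(
    list(param_axis = param_axis, beta_axis = beta_axis, mass = mass),
    class = "vbdm_grid"
  )
}

#' Default estimation grid for a task kind
#'
#' @param task_kind Task kind string.
#' @param n_param,n_beta Grid resolutions.
#' @return A uniform `vbdm_grid`.
#' @export
default_grid <- function(task_kind, n_param = 41L, n_beta = 11L) {
  param_axis <- if (task_kind == "mixed_gamble") {
    seq(-2, 2, length.out = n_param)
  } else {
    seq(-7, 2, length.out = n_param)
  }
  posterior_grid(param_axis, seq(-3, 2, length.out = n_beta))
}

#' One two-option trial offer
#'
#' Option A is the certain/sooner side (for probability-of-loss trials a
#' certain loss, stored negative); option B is the delayed/probabilistic side
#' or, for mixed gambles, the 50/50 gamble against rejecting (value 0).
#'
#' @param task_kind Task kind string.
#' @param option_a_amount,option_b_amount Euro amounts (negative in loss
#'   framing); `NA` for mixed gambles.
#' @param delay_days Delay of option B, days (delay task only).
#' @param probability Probability of option B's outcome (probability tasks).
#' @param gain,loss Mixed-gamble outcomes, euros (magnitudes).
#' @return A `vbdm_offer` list.
#' @export
task_offer <- function(task_kind, option_a_amount = NA_real_,
                       option_b_amount = NA_real_, delay_days = NA_real_,
                       probability = NA_real_, gain = NA_real_,
                       loss = NA_real_) {
  structure(
    list(task_kind = task_kind, option_a_amount = option_a_amount,
         option_b_amount = option_b_amount, delay_days = delay_days,
         probability = probability, gain = gain, loss = loss),
    class = "vbdm_offer"
  )
}

# Subjective values of both options under candidate log-parameter values.
# `log_param` may be a vector; returns list(va, vb) of the same length.
offer_values <- function(offer, log_param) {
  switch(offer$task_kind,
    delay = {
      k <- exp(log_param)
      list(va = rep(offer$option_a_amount, length(k)),
           vb = offer$option_b_amount / (1 + k * offer$delay_days))
    },
    prob_gain = ,
    prob_loss = {
      k <- exp(log_param)
      theta <- (1 - offer$probability) / offer$probability
      list(va = rep(offer$option_a_amount, length(k)),
           vb = offer$option_b_amount / (1 + k * theta))
    },
    mixed_gamble = {
      lam <- exp(log_param)
      list(va = rep(0, length(lam)),
           vb = 0.5 * offer$gain - 0.5 * lam * offer$loss)
    },
    stop("unknown task kind: ", offer$task_kind)
  )
}

# Likelihood of an observed choice at every grid node.
# Returns a matrix param x beta.
choice_likelihood <- function(grid, offer, choice) {
  stopifnot(choice %in% c("a", "b"))
  v <- offer_values(offer, grid$param_axis)
  dv <- v$vb - v$va
  beta <- exp(grid$beta_axis)
  p_b <- stats::plogis(outer(dv, beta))
  if (choice == "b") p_b else 1 - p_b
}

#' Bayes update of the posterior grid after one trial
#'
#' Re-weights every grid node by the likelihood of the observed choice under
#' that node's parameters (logistic choice rule) and renormalises. Total mass
#' is restored to 1 within 1e-9.
#'
#' @param grid A `vbdm_grid`.
#' @param offer The presented `vbdm_offer`.
#' @param choice `"a"` or `"b"`.
#' @return The updated `vbdm_grid`.
#' @export
bayes_update <- function(grid, offer, choice) {
  lik <- choice_likelihood(grid, offer, choice)
  mass <- grid$mass * lik
  total <- sum(mass)
  if (!is.finite(total) || total <= 0) {
    stop("degenerate update: the observed choice has zero likelihood on ",
         "every grid node (task ", offer$task_kind, ")")
  }
  grid$mass <- mass / total
  grid
}

#' Posterior summaries of the decision parameter
#'
#' `grid_posterior_mean()` returns the marginal posterior mean of the
#' log-scale decision parameter; `grid_map()` the maximum a posteriori node
#' (ties broken toward the smallest parameter value, deterministically).
#'
#' @param grid A `vbdm_grid`.
#' @return A scalar on the log-parameter scale.
#' @export
grid_posterior_mean <- function(grid) {
  sum(grid$param_axis * rowSums(grid$mass))
}

#' @rdname grid_posterior_mean
#' @export
grid_map <- function(grid) {
  marg <- rowSums(grid$mass)
  grid$param_axis[which.max(marg)]  # which.max takes the first (smallest)
}
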