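#' Task configuration for the decision-making battery
#'
#' Defaults reproduce the battery layout: three discounting tasks of 30
#' trials each with amounts between 0.30 and 10.00 euros (delay menu
#' 3/7/14/31/61/180/365 days; probability menu 2/3, 1/2, 1/3, 1/4, 1/5), and
#' a 40-trial mixed-gambles task with gains in 1-40 euros, losses in 5-20
#' euros (on a 0.50 euro lattice) and a 10 euro endowment. The endowment is
#' bookkeeping only; utilities carry no wealth term.
#'
#' @param task_kind One of `"delay"`, `"prob_gain"`, `"prob_loss"`,
#'   `"mixed_gamble"`.
#' @param n_trials Number of trials; defaults to 30 (discounting) or 40
#'   (mixed gambles).
#' @param amount_range Range of the adaptable certain/sooner amount, euros.
#' @param fixed_amount Magnitude of the fixed delayed/probabilistic option.
#' @param delays Delay menu in days.
#' @param probabilities Probability menu.
#' @param gamble_gain_range,gamble_loss_range Gain and loss ranges for the
#'   mixed-gambles task, euros.
#' @param gamble_loss_step Lattice step for the sampled loss, euros.
#' @param endowment Starting endowment for the mixed-gambles task, euros.
#' @return A `vbdm_task_config` list.
#' @export
task_config <- function(task_kind = c("delay", "prob_gain", "prob_loss",
                                      "mixed_gamble"),
                        n_trials = NULL,
                        amount_range = c(0.30, 10.00),
                        fixed_amount = 10.00,
                        delays = c(3, 7, 14, 31, 61, 180, 365),
                        probabilities = c(2 / 3, 1 / 2, 1 / 3, 1 / 4, 1 / 5),
                        gamble_gain_range = c(1, 40),
                        gamble_loss_range = c(5, 20),
                        gamble_loss_step = 0.5,
                        endowment = 10) {
  task_kind <- match.arg(task_kind)
  if (is.null(n_trials)) {
    n_trials <- if (task_kind == "mixed_gamble") 40L else 30L
  }
  n_trials <- as.integer(n_trials)
  stopifnot(n_trials >= 1)
  if (length(delays) < 1 || length(probabilities) < 1) {
    stop("delay and probability menus must be non-empty")
  }
  if (diff(amount_range) <= 0 || diff(gamble_gain_range) <= 0 ||
      diff(gamble_loss_range) < 0) {
    stop("ranges must be ordered (low, high)")
  }
  if (any(probabilities <= 0) || any(probabilities > 1)) {
    stop("probabilities must lie in (0, 1]")
  }
  structure(
    list(
      task_kind = task_kind,
      n_trials = n_trials,
      amount_range = amount_range,
      fixed_amount = fixed_amount,
      delays = delays,
      probabilities = probabilities,
      gamble_gain_range = gamble_gain_range,
      gamble_loss_range = gamble_loss_range,
      gamble_loss_step = gamble_loss_step,
      endowment = endowment
    ),
    class = "vbdm_task_config"
  )
}

#' Agent (simulated participant) decision parameters
#'
#' True generative parameters for one simulated participant: one log
#' discounting rate per discounting task, a log loss-aversion coefficient for
#' the mixed-gambles task, and a choice-consistency `beta` (shared across
#' tasks unless a named vector is supplied).
#'
#' @param log_k_delay,log_k_pgain,log_k_ploss Log discounting rates.
#' @param log_lambda Log loss aversion.
#' @param beta Choice consistency (>= 0); scalar or named per task kind.
#' @return A `vbdm_agent` list.
#' @export
agent_params <- function(log_k_delay = -4, log_k_pgain = 0, log_k_ploss = 0,
                         log_lambda = 0.3, beta = 5) {
  pars <- c(log_k_delay, log_k_pgain, log_k_ploss, log_lambda)
  if (any(!is.finite(pars))) stop("decision parameters must be finite")
  if (any(beta < 0) || any(!is.finite(beta))) stop("`beta` must be >= 0")
  structure(
    list(log_k_delay = log_k_delay, log_k_pgain = log_k_pgain,
         log_k_ploss = log_k_ploss, log_lambda = log_lambda, beta = beta),
    class = "vbdm_agent"
  )
}

# True parameter and beta for one task kind
agent_task_params <- function(agent, task_kind) {
  param <- switch(task_kind,
    delay = agent$log_k_delay,
    prob_gain = agent$log_k_pgain,
    prob_loss = agent$log_k_ploss,
    mixed_gamble = agent$log_lambda
  )
  beta <- agent$beta
  if (!is.null(names(beta)) && task_kind %in% names(beta)) {
    beta <- beta[[task_kind]]
  } else {
    beta <- beta[[1]]
  }
  list(param = param, beta = beta)
}
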