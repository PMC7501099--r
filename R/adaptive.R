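#' Construct the next, maximally informative offer
#'
#' The adaptive rule places the two options at the indifference point implied
#' by the current posterior-mean parameter (posterior mean of the log
#' parameter, exponentiated), so each trial is asked where the participant's
#' choice is least predictable and most informative. The delay or probability
#' is drawn uniformly from the configured menu using the current RNG stream;
#' the adjustable amount is rounded to 0.01 euro and clipped to the
#' configured range.
#'
#' Task-specific layout:
#' * delay / probability-of-gains: the certain/sooner amount is adapted
#'   against the fixed 10-euro delayed/probabilistic reward;
#' * probability-of-losses: both options are losses (negative amounts); the
#'   certain loss is adapted against a fixed 10-euro probabilistic loss;
#' * mixed gambles: the loss is drawn uniformly on a 0.50-euro lattice in
#'   5-20 and the gain set to `posterior-mean lambda x loss`, clipped to
#'   1-40.
#'
#' On the first trial the grid is uniform, so the posterior mean equals the
#' grid midpoint and the offer sits at the grid-median parameter's
#' indifference point.
#'
#' @param grid Current `vbdm_grid`.
#' @param config A `vbdm_task_config`.
#' @return A `vbdm_offer`.
#' @export
select_offer <- function(grid, config) {
  kind <- config$task_kind
  par_hat <- exp(grid_posterior_mean(grid))
  clip <- function(x, rng) pmin(pmax(x, rng[1]), rng[2])
  draw <- function(menu) menu[sample.int(length(menu), 1L)]
  if (kind == "delay") {
    d <- draw(config$delays)
    a <- clip(round(config$fixed_amount / (1 + par_hat * d), 2),
              config$amount_range)
    task_offer("delay", option_a_amount = a,
               option_b_amount = config$fixed_amount, delay_days = d)
  } else if (kind == "prob_gain") {
    p <- draw(config$probabilities)
    theta <- (1 - p) / p
    a <- clip(round(config$fixed_amount / (1 + par_hat * theta), 2),
              config$amount_range)
    task_offer("prob_gain", option_a_amount = a,
               option_b_amount = config$fixed_amount, probability = p)
  } else if (kind == "prob_loss") {
    p <- draw(config$probabilities)
    theta <- (1 - p) / p
    a <- clip(round(config$fixed_amount / (1 + par_hat * theta), 2),
              config$amount_range)
    task_offer("prob_loss", option_a_amount = -a,
               option_b_amount = -config$fixed_amount, probability = p)
  } else if (kind == "mixed_gamble") {
    lattice <- seq(config$gamble_loss_range[1], config$gamble_loss_range[2],
                   by = config$gamble_loss_step)
    loss <- draw(lattice)
    gain <- clip(round(par_hat * loss, 2), config$gamble_gain_range)
    task_offer("mixed_gamble", gain = gain, loss = loss)
  } else {
    stop("unknown task kind: ", kind)
  }
}

# Simulate the agent's choice on one offer using the logistic rule.
simulate_choice <- function(offer, agent) {
  tp <- agent_task_params(agent, offer$task_kind)
  v <- offer_values(offer, tp$param)
  p_b <- choice_probability(v$vb, v$va, tp$beta)
  if (stats::runif(1) < p_b) "b" else "a"
}

#' Run one adaptive session for a simulated agent
#'
#' Executes `n_trials` cycles of offer selection, simulated choice, and
#' posterior update, and returns the trial log together with posterior-mean
#' and MAP estimates of the session's decision parameter (log scale).
#' Identical `agent`, `config`, and `seed` give a bit-identical session.
#'
#' @param agent A `vbdm_agent`.
#' @param config A `vbdm_task_config`.
#' @param seed Integer seed for the session RNG.
#' @param grid Optional starting `vbdm_grid`; defaults to the task's uniform
#'   default grid.
#' @return A `vbdm_session` list with elements `choices` (data frame),
#'   `estimate` (named vector `mean`, `map`), `final_grid`, `seed`,
#'   `task_kind`.
#' @export
run_session <- function(agent, config, seed, grid = NULL) {
  stopifnot(inherits(agent, "vbdm_agent"), inherits(config, "vbdm_task_config"))
  if (is.null(grid)) grid <- default_grid(config$task_kind)
  set.seed(seed)
  n <- config$n_trials
  log <- data.frame(
    trial = seq_len(n), task = config$task_kind,
    option_a_amount = NA_real_, option_b_amount = NA_real_,
    delay_days = NA_real_, probability = NA_real_,
    gain = NA_real_, loss = NA_real_, choice = NA_character_,
    seed = seed, stringsAsFactors = FALSE
  )
  for (t in seq_len(n)) {
    offer <- select_offer(grid, config)
    choice <- simulate_choice(offer, agent)
    grid <- bayes_update(grid, offer, choice)
    log$option_a_amount[t] <- offer$option_a_amount
    log$option_b_amount[t] <- offer$option_b_amount
    log$delay_days[t] <- offer$delay_days
    log$probability[t] <- offer$probability
    log$gain[t] <- offer$gain
    log$loss[t] <- offer$loss
    log$choice[t] <- choice
  }
  structure(
    list(choices = log,
         estimate = c(mean = grid_posterior_mean(grid), map = grid_map(grid)),
         final_grid = grid, seed = seed, task_kind = config$task_kind),
    class = "vbdm_session"
  )
}

#' Run the full four-task battery for one agent
#'
#' @param agent A `vbdm_agent`.
#' @param seed Integer; per-task seeds are derived as `seed + 0:3`.
#' @param configs Optional named list of task configs.
#' @return Named list of `vbdm_session` objects keyed by task kind.
#' @export
run_battery <- function(agent, seed,
                        configs = lapply(
                          stats::setNames(nm = c("delay", "prob_gain",
                                                 "prob_loss", "mixed_gamble")),
                          task_config)) {
  out <- vector("list", length(configs))
  names(out) <- names(configs)
  for (i in seq_along(configs)) {
    out[[i]] <- run_session(agent, configs[[i]], seed = seed + i - 1L)
  }
  out
}

#' Write / read a session choice log as CSV
#'
#' Columns: trial, task, option_a_amount, option_b_amount, delay_days,
#' probability, gain, loss, choice, seed.
#'
#' @param session A `vbdm_session`.
#' @param path File path.
#' @return `read_choice_log()` returns the choice-log data frame.
#' @export
write_choice_log <- function(session, path) {
  utils::write.csv(session$choices, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choice_log
#' @export
read_choice_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write battery estimates as JSON keyed by task kind
#'
#' @param sessions Named list of `vbdm_session` objects.
#' @param path File path.
#' @export
write_estimates_json <- function(sessions, path) {
  est <- lapply(sessions, function(s) {
    list(task_kind = s$task_kind, seed = s$seed,
         posterior_mean = unname(s$estimate["mean"]),
         map = unname(s$estimate["map"]))
  })
  jsonlite::write_json(est, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
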