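test_that("offers sit at the posterior-mean indifference point", {
  # no discounting: certain amount equals (and is clipped at) the maximum
  grid0 <- posterior_grid(param_axis = c(-30, -29), beta_axis = 0)
  cfg <- task_config("delay", delays = 14)
  set.seed(1)
  offer <- select_offer(grid0, cfg)
  expect_equal(offer$option_a_amount, 10)

  # posterior mean k = 0.1, delay 14: indifference amount 10/2.4 -> 4.17
  grid <- posterior_grid(param_axis = c(log(0.05), log(0.1)), beta_axis = 0,
                         mass = matrix(c(0, 1), 2, 1))
  offer <- select_offer(grid, cfg)
  expect_equal(offer$option_a_amount, 4.17)
  expect_equal(offer$delay_days, 14)

  # mixed gamble at posterior-mean lambda = 2, loss 10 -> gain 20
  gridg <- posterior_grid(param_axis = c(log(1), log(2)), beta_axis = 0,
                          mass = matrix(c(0, 1), 2, 1))
  cfgg <- task_config("mixed_gamble", gamble_loss_range = c(10, 10))
  offer <- select_offer(gridg, cfgg)
  expect_equal(offer$loss, 10)
  expect_equal(offer$gain, 20)

  # probability-of-losses offers are negative on both sides
  gridp <- default_grid("prob_loss")
  cfgp <- task_config("prob_loss")
  offer <- select_offer(gridp, cfgp)
  expect_lt(offer$option_a_amount, 0)
  expect_equal(offer$option_b_amount, -10)
})

test_that("offers respect the configured menus and amount ranges", {
  set.seed(2)
  for (kind in c("delay", "prob_gain", "prob_loss")) {
    cfg <- task_config(kind)
    grid <- default_grid(kind)
    for (i in 1:15) {
      offer <- select_offer(grid, cfg)
      expect_true(abs(offer$option_a_amount) >= cfg$amount_range[1])
      expect_true(abs(offer$option_a_amount) <= cfg$amount_range[2])
      if (kind == "delay") {
        expect_true(offer$delay_days %in% cfg$delays)
      } else {
        expect_true(any(abs(offer$probability - cfg$probabilities) < 1e-12))
      }
      grid <- bayes_update(grid, offer, sample(c("a", "b"), 1))
    }
  }
})

test_that("sessions replay bit-identically under the same seed", {
  agent <- agent_params(log_k_delay = -2, beta = 8)
  cfg <- task_config("delay")
  s1 <- run_session(agent, cfg, seed = 99)
  s2 <- run_session(agent, cfg, seed = 99)
  expect_identical(s1$choices, s2$choices)
  expect_identical(s1$estimate, s2$estimate)
  expect_equal(nrow(s1$choices), cfg$n_trials)
  s3 <- run_session(agent, cfg, seed = 100)
  expect_false(identical(s1$choices$choice, s3$choices$choice))
})

test_that("a pure-noise agent leaves the posterior near the prior mean", {
  # random responding carries no directional information about the rate:
  # averaged over sessions the estimate stays at the uniform-grid mean,
  # and the posterior remains far more dispersed than a consistent agent's
  agent <- agent_params(log_k_delay = -2, beta = 0)
  sessions <- lapply(1:20, function(s) {
    run_session(agent, task_config("delay"), seed = 700 + s)
  })
  est <- sapply(sessions, function(s) s$estimate[["mean"]])
  expect_lt(abs(mean(est) - mean(default_grid("delay")$param_axis)), 1)
  marg_sd <- function(s) {
    m <- rowSums(s$final_grid$mass)
    ax <- s$final_grid$param_axis
    sqrt(sum(ax^2 * m) - sum(ax * m)^2)
  }
  consistent <- run_session(agent_params(log_k_delay = -2, beta = 20),
                            task_config("delay"), seed = 1)
  expect_gt(mean(sapply(sessions, marg_sd)), 2 * marg_sd(consistent))
})

test_that("a consistent agent's discount rate is recovered from 30 trials", {
  agent <- agent_params(log_k_delay = -2, beta = 20)
  err <- sapply(1:20, function(s) {
    run_session(agent, task_config("delay"), seed = s)$estimate["mean"] + 2
  })
  expect_lt(median(abs(err)), 0.5)
})

test_that("loss aversion is recovered from a 40-trial mixed-gamble session", {
  agent <- agent_params(log_lambda = log(1.5), beta = 20)
  err <- sapply(1:20, function(s) {
    run_session(agent, task_config("mixed_gamble"),
                seed = s)$estimate["mean"] - log(1.5)
  })
  expect_lt(median(abs(err)), 0.3)
})

test_that("true and estimated parameters correlate strongly across agents", {
  set.seed(31)
  n <- 30
  true <- runif(n, -5, 1)
  est <- sapply(seq_len(n), function(i) {
    run_session(agent_params(log_k_delay = true[i], beta = 20),
                task_config("delay"), seed = 400 + i)$estimate["mean"]
  })
  expect_gt(cor(true, est, method = "spearman"), 0.8)
})

test_that("choice logs and estimates round-trip through CSV and JSON", {
  agent <- agent_params(beta = 10)
  s <- run_session(agent, task_config("prob_gain"), seed = 3)
  csv <- tempfile(fileext = ".csv")
  write_choice_log(s, csv)
  back <- read_choice_log(csv)
  expect_equal(back$choice, s$choices$choice)
  expect_equal(back$option_a_amount, s$choices$option_a_amount)

  js <- tempfile(fileext = ".json")
  write_estimates_json(list(prob_gain = s), js)
  est <- jsonlite::read_json(js)
  expect_equal(est$prob_gain$posterior_mean, unname(s$estimate["mean"]),
               tolerance = 1e-12)
  unlink(c(csv, js))
})
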