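test_that("grid mass stays normalised and non-negative through updates", {
  set.seed(1)
  grid <- default_grid("delay")
  cfg <- task_config("delay")
  for (i in 1:20) {
    offer <- select_offer(grid, cfg)
    choice <- sample(c("a", "b"), 1)
    grid <- bayes_update(grid, offer, choice)
    expect_equal(sum(grid$mass), 1, tolerance = 1e-9)
    expect_true(all(grid$mass >= 0))
  }
})

test_that("an offer with identical options leaves a uniform grid unchanged", {
  grid <- default_grid("delay")
  offer <- task_offer("delay", option_a_amount = 10, option_b_amount = 10,
                      delay_days = 0)
  out <- bayes_update(grid, offer, "b")
  expect_equal(out$mass, grid$mass, tolerance = 1e-12)
})

test_that("pointwise Bayes rule shifts mass toward the consistent node", {
  # two candidate rates: near-zero discounting vs extreme discounting
  grid <- posterior_grid(param_axis = c(log(0.001), log(10)),
                         beta_axis = 0)  # beta = 1
  offer <- task_offer("delay", option_a_amount = 5, option_b_amount = 10,
                      delay_days = 365)
  out <- bayes_update(grid, offer, "b")  # chose the delayed reward
  # hand computation: P(b | k = 0.001) = plogis(10/1.365 - 5),
  #                   P(b | k = 10)    = plogis(10/3651 - 5)
  l1 <- stats::plogis(10 / (1 + 0.001 * 365) - 5)
  l2 <- stats::plogis(10 / (1 + 10 * 365) - 5)
  expect_equal(rowSums(out$mass), c(l1, l2) / (l1 + l2), tolerance = 1e-12)
  expect_gt(rowSums(out$mass)[1], 0.5)
})

test_that("sequential updating equals the brute-force joint likelihood", {
  # 3 x 3 grid, three fixed trials: product of per-trial likelihoods,
  # normalised once, must equal the sequential posterior
  grid0 <- posterior_grid(param_axis = c(-4, -2, 0),
                          beta_axis = c(-1, 0, 1))
  offers <- list(
    task_offer("delay", option_a_amount = 4, option_b_amount = 10,
               delay_days = 31),
    task_offer("delay", option_a_amount = 7.5, option_b_amount = 10,
               delay_days = 180),
    task_offer("delay", option_a_amount = 2, option_b_amount = 10,
               delay_days = 365)
  )
  choices <- c("b", "a", "b")
  grid <- grid0
  for (i in 1:3) grid <- bayes_update(grid, offers[[i]], choices[[i]])

  brute <- grid0$mass
  for (i in 1:3) {
    for (r in 1:3) {
      for (cc in 1:3) {
        k <- exp(grid0$param_axis[r]); beta <- exp(grid0$beta_axis[cc])
        vb <- 10 / (1 + k * offers[[i]]$delay_days)
        va <- offers[[i]]$option_a_amount
        p_b <- 1 / (1 + exp(-beta * (vb - va)))
        brute[r, cc] <- brute[r, cc] *
          (if (choices[[i]] == "b") p_b else 1 - p_b)
      }
    }
  }
  brute <- brute / sum(brute)
  expect_equal(grid$mass, brute, tolerance = 1e-12)
})

test_that("repeated consistent trials converge toward the consistent node", {
  grid <- posterior_grid(param_axis = seq(-6, 1, length.out = 15),
                         beta_axis = c(0, 1))
  offer <- task_offer("delay", option_a_amount = 5, option_b_amount = 10,
                      delay_days = 180)
  means <- numeric(20)
  for (i in 1:20) {
    grid <- bayes_update(grid, offer, "b")
    means[i] <- grid_posterior_mean(grid)
  }
  expect_true(all(diff(means) < 1e-12))  # monotone toward low log k
})

test_that("MAP ties break toward the smallest parameter value", {
  grid <- posterior_grid(param_axis = c(-2, 0, 2), beta_axis = 0,
                         mass = matrix(c(0.4, 0.2, 0.4), 3, 1))
  expect_equal(grid_map(grid), -2)
})
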