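test_that("vague priors reproduce ordinary least squares", {
  set.seed(5)
  n <- 200
  d <- data.frame(x = rnorm(n))
  d$y <- 0.5 * d$x + rnorm(n)
  fit <- fit_bayes_lm(y ~ x, d, mcmc = quick_mcmc(2))
  ols <- coef(lm(y ~ x, d))
  cs <- coef_summary(fit)
  expect_equal(cs$mean[cs$term == "x"], unname(ols["x"]), tolerance = 0.01)
  expect_equal(cs$mean[cs$term == "(Intercept)"], unname(ols[1]),
               tolerance = 0.01)
})

test_that("an informative prior pulls the posterior to the conjugate form", {
  d <- forced_ols_data(300, slope = 0.10, se = 0.0485, seed = 4)
  lik <- fit_likelihood_lm(y ~ x, d, "x")
  expect_equal(lik$mean, 0.10, tolerance = 1e-9)
  expect_equal(lik$sd, 0.0485, tolerance = 1e-9)
  prior <- normal_summary(0.25, 0.1276)
  fit <- fit_bayes_lm(y ~ x, d, priors = list(x = prior),
                      mcmc = quick_mcmc(6))
  closed <- combine_normal_summaries(prior, lik)
  cs <- coef_summary(fit)
  expect_equal(cs$mean[cs$term == "x"], closed$mean, tolerance = 0.01)
})

test_that("identical seeds give identical chains", {
  set.seed(1)
  d <- data.frame(x = rnorm(80))
  d$y <- 0.3 * d$x + rnorm(80)
  f1 <- fit_bayes_lm(y ~ x, d, mcmc = quick_mcmc(9))
  f2 <- fit_bayes_lm(y ~ x, d, mcmc = quick_mcmc(9))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_bayes_lm(y ~ x, d, mcmc = quick_mcmc(10))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the chain keeps the configured number of thinned draws", {
  set.seed(2)
  d <- data.frame(x = rnorm(50)); d$y <- d$x + rnorm(50)
  mc <- mcmc_config(burn_in = 100, draws = 1100, thinning = 2, seed = 1)
  fit <- fit_bayes_lm(y ~ x, d, mcmc = mc)
  expect_equal(nrow(fit$draws), 500)
  expect_error(mcmc_config(burn_in = 200, draws = 100), "draws > burn_in")
})

test_that("rank-deficient designs are rejected", {
  d <- data.frame(x = 1:10, y = rnorm(10))
  d$x2 <- 2 * d$x
  expect_error(fit_bayes_lm(y ~ x + x2, d, mcmc = quick_mcmc()),
               "rank-deficient")
})

test_that("group contrasts count ties as half", {
  expect_equal(group_contrast(c(1, 2, 3), c(1, 2, 3)), 50)
  expect_equal(group_contrast(c(2, 3, 4), c(1, 2, 3)), 100)
  expect_error(group_contrast(1:3, 1:4), "equal length")
})

test_that("group differences are detected with the expected direction", {
  coh <- generate_cohort(cohort_config(seed = 14))
  res <- fit_group_difference(coh, "delay", mcmc = quick_mcmc(3))
  # prior 0.37 plus a positive generating shift: strong positive evidence
  expect_gt(res$sud$probability, 90)
  expect_true(res$contrast_pct_above >= 0 && res$contrast_pct_above <= 100)
  expect_equal(res$direction, "greater")
})

test_that("interaction terms recover a group-specific association", {
  # association only in the ND group (-0.4) vs controls (0): the ND
  # interaction should show up in the hypothesised (negative) direction
  as1 <- default_assoc(); as1[] <- 0
  probs <- sapply(1:3, function(s) {
    coh <- generate_cohort(cohort_config(assoc = as1, seed = 20 + s))
    nd <- coh$group == "ND"
    extra <- -0.4 * coh$z_loglambda[nd] * cohort_config()$criteria_scale
    coh$nd_criteria_fu[nd] <- pmax(0, round(coh$nd_criteria_fu[nd] + extra))
    fit_prediction(coh, "loss_aversion", "nd_criteria",
                   mcmc = quick_mcmc(s), interaction = TRUE
                   )$interaction_nd$probability
  })
  expect_gt(mean(probs), 80)
})
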