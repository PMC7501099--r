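# Short chain for tests that only need Monte-Carlo agreement, not the full
# production chain length.
quick_mcmc <- function(seed = 1L) {
  mcmc_config(burn_in = 500L, draws = 10000L, thinning = 2L, seed = seed)
}

# Construct (x, y) whose OLS slope and slope SE are exactly the requested
# values: the residual is orthogonalised against x and rescaled.
forced_ols_data <- function(n, slope, se, seed = 1) {
  set.seed(seed)
  x <- as.numeric(scale(rnorm(n)))
  e <- stats::resid(stats::lm(rnorm(n) ~ x))
  # SE = sqrt(sum(e^2) / (n - 2)) / sqrt(sum((x - mean(x))^2))
  target_ss <- se^2 * sum((x - mean(x))^2) * (n - 2)
  e <- e * sqrt(target_ss / sum(e^2))
  data.frame(x = x, y = slope * x + e)
}
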