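#' MCMC settings for the Bayesian linear model
#'
#' Defaults mirror the analysis protocol: 100,000 simulations with a burn-in
#' of 5000 and thinning of two, so (100000 - 5000) / 2 = 47,500 retained
#' draws.
#'
#' @param burn_in Burn-in iterations discarded from the front of the chain.
#' @param draws Total MCMC iterations.
#' @param thinning Keep every `thinning`-th post-burn-in iteration.
#' @param seed Integer seed for the chain.
#' @return A `vbdm_mcmc_config` list.
#' @export
mcmc_config <- function(burn_in = 5000L, draws = 100000L, thinning = 2L,
                        seed = 1L) {
  burn_in <- as.integer(burn_in); draws <- as.integer(draws)
  thinning <- as.integer(thinning)
  stopifnot(draws > burn_in, burn_in > 0, thinning >= 1)
  structure(list(burn_in = burn_in, draws = draws, thinning = thinning,
                 seed = as.integer(seed)),
            class = "vbdm_mcmc_config")
}

#' Bayesian linear regression with independent normal coefficient priors
#'
#' Gibbs sampler for `y = X b + e`, `e ~ N(0, sigma^2)`, with independent
#' normal priors on the coefficients and an inverse-gamma(0.01, 0.01) prior
#' on the residual variance. Conditional on `sigma^2` the coefficient draw is
#' exact multivariate normal; conditional on `b` the variance draw is exact
#' inverse-gamma. Terms without an entry in `priors` get the vague
#' N(0, var 1e4) prior, so their posterior means match ordinary least squares
#' within Monte-Carlo error.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param priors Named list mapping design-matrix column names to
#'   `vbdm_normal` priors (or `c(mean, sd)` pairs).
#' @param mcmc A `vbdm_mcmc_config`.
#' @return A `vbdm_blm` object: `draws` (matrix, kept iterations x
#'   coefficients), `sigma2` (kept residual-variance draws), `terms`
#'   (coefficient names), `n`.
#' @export
fit_bayes_lm <- function(formula, data, priors = list(),
                         mcmc = mcmc_config()) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient design matrix")
  unknown <- setdiff(names(priors), colnames(X))
  if (length(unknown)) {
    stop("priors given for terms not in the design: ",
         paste(unknown, collapse = ", "))
  }
  m0 <- rep(0, p); v0 <- rep(1e4, p)
  for (nm in names(priors)) {
    pr <- as_normal(priors[[nm]])
    j <- match(nm, colnames(X))
    m0[j] <- pr$mean; v0[j] <- pr$sd^2
  }
  a0 <- 0.01; b0 <- 0.01
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  set.seed(mcmc$seed)
  keep_idx <- seq(mcmc$burn_in + mcmc$thinning, mcmc$draws, by = mcmc$thinning)
  n_keep <- length(keep_idx)
  draws <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  sigma2_draws <- numeric(n_keep)
  sigma2 <- stats::var(stats::lm.fit(X, y)$residuals)
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  k <- 0L
  for (it in seq_len(mcmc$draws)) {
    v_inv <- XtX / sigma2 + diag(1 / v0, p)
    ch <- chol(v_inv)
    rhs <- Xty / sigma2 + m0 / v0
    b_mean <- backsolve(ch, forwardsolve(t(ch), rhs))
    b <- b_mean + backsolve(ch, stats::rnorm(p))
    resid <- y - X %*% b
    sigma2 <- 1 / stats::rgamma(1, a0 + n / 2,
                                rate = b0 + sum(resid^2) / 2)
    if (k < n_keep && it == keep_idx[k + 1L]) {
      k <- k + 1L
      draws[k, ] <- b
      sigma2_draws[k] <- sigma2
    }
  }
  structure(list(draws = draws, sigma2 = sigma2_draws,
                 terms = colnames(X), n = n, formula = formula),
            class = "vbdm_blm")
}

#' Posterior summary of a fitted Bayesian linear model
#'
#' @param fit A `vbdm_blm`.
#' @param level Interval coverage.
#' @return Data frame: term, mean, sd, ci_low, ci_high.
#' @export
coef_summary <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  data.frame(
    term = fit$terms,
    mean = colMeans(fit$draws),
    sd = apply(fit$draws, 2, stats::sd),
    ci_low = apply(fit$draws, 2, stats::quantile, probs = a),
    ci_high = apply(fit$draws, 2, stats::quantile, probs = 1 - a),
    row.names = NULL
  )
}

#' Directional posterior result for one coefficient
#'
#' @param fit A `vbdm_blm`.
#' @param term Coefficient name.
#' @param direction `"greater"` or `"less"`.
#' @return List: `summary` (`vbdm_normal` moment summary of the draws),
#'   `direction`, `probability` (percent of draws in the direction).
#' @export
directional_result <- function(fit, term, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  j <- match(term, fit$terms)
  if (is.na(j)) stop("no such term: ", term)
  d <- fit$draws[, j]
  list(summary = normal_summary(mean(d), stats::sd(d)),
       direction = direction,
       probability = directional_probability(d, direction))
}

#' Posterior contrast between two group coefficients
#'
#' Elementwise difference of paired posterior draws (SUD-vs-control minus
#' ND-vs-control from one fitted model); returns the percentage of draws
#' above zero, differences exactly at zero counting half.
#'
#' @param draws_sud,draws_nd Equal-length draw vectors.
#' @return Percentage in \[0, 100\].
#' @export
group_contrast <- function(draws_sud, draws_nd) {
  if (length(draws_sud) != length(draws_nd)) {
    stop("draw vectors must have equal length")
  }
  directional_probability(draws_sud - draws_nd, "greater")
}

#' Ordinary least-squares "likelihood" summary of one coefficient
#'
#' Fits the model by OLS and returns the coefficient's estimate and standard
#' error as a normal summary with a Wald 95% interval — the flat-prior
#' (data-only) distribution shown alongside prior and posterior in the
#' analysis tables.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param term Coefficient name.
#' @return A `vbdm_normal`.
#' @export
fit_likelihood_lm <- function(formula, data, term) {
  fit <- stats::lm(formula, data)
  est <- summary(fit)$coefficients
  if (!term %in% rownames(est)) stop("no such term: ", term)
  normal_summary(est[term, "Estimate"], est[term, "Std. Error"])
}
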