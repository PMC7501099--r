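#' Reverse-Bayes prior sensitivity analysis
#'
#' Finds the most pessimistic prior mean that still supports the hypothesised
#' conclusion: starting from the current prior mean, the mean is moved
#' against the hypothesised direction in steps of 0.1 (variance unchanged),
#' the posterior is recomputed by precision-weighted combination with the
#' likelihood at each step, and the walk stops when the directional posterior
#' probability first drops below the threshold. Because the posterior mean is
#' linear in the prior mean with constant sd, the probability trace is
#' monotone along the walk.
#'
#' @param likelihood `vbdm_normal` summary of the data (likelihood) for the
#'   coefficient.
#' @param prior_var Prior variance, held fixed along the walk.
#' @param direction `"greater"` or `"less"`.
#' @param threshold Posterior probability required to keep the conclusion,
#'   as a fraction (default 0.95).
#' @param step Step size for the prior-mean walk (default 0.1).
#' @param start_mean Prior mean to start from.
#' @param anchor `"start"` walks from `start_mean` itself; `"decimal"` snaps
#'   the walk onto the 0.1 lattice (first candidate is the nearest lattice
#'   point at or below `start_mean` for "greater", at or above for "less").
#' @param max_steps Maximum number of steps to take beyond the start.
#' @return A list: `mean` (most pessimistic passing prior mean, or `NA` if
#'   even the start fails), `passed` (logical), and `trace` (data frame of
#'   prior mean and posterior directional probability in percent).
#' @export
reverse_bayes <- function(likelihood, prior_var, direction = c("greater",
                                                               "less"),
                          threshold = 0.95, step = 0.1, start_mean,
                          anchor = c("start", "decimal"), max_steps = 60L) {
  direction <- match.arg(direction)
  anchor <- match.arg(anchor)
  stopifnot(threshold > 0, threshold < 1, step > 0, prior_var > 0)
  likelihood <- as_normal(likelihood)
  sgn <- if (direction == "greater") 1 else -1
  first <- if (anchor == "decimal") {
    sgn * floor(sgn * start_mean / step) * step
  } else {
    start_mean
  }
  means <- first - sgn * step * (0:max_steps)
  prob <- vapply(means, function(m) {
    post <- combine_normal_summaries(normal_summary(m, sqrt(prior_var)),
                                     likelihood)
    directional_probability(post, direction)
  }, numeric(1))
  pass <- prob >= 100 * threshold
  n_keep <- if (all(pass)) length(means) else which(!pass)[1]
  trace <- data.frame(prior_mean = means[seq_len(n_keep)],
                      probability = prob[seq_len(n_keep)])
  list(
    mean = if (pass[1]) means[max(which(pass))] else NA_real_,
    passed = pass[1],
    trace = trace
  )
}
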