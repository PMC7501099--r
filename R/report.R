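#' Published prior/likelihood/posterior summary rows
#'
#' Reads the bundled transcription of the published Bayesian regression
#' summary tables: for every analysis block (group differences per task and
#' group; one-year predictions per task and outcome) the prior, likelihood,
#' and posterior rows, each with mean and central 95% interval, the
#' hypothesised direction, and the published directional probability (whole
#' percent) on the posterior row. These printed summaries are inputs: they
#' anchor the conjugate-combination checks and the cohort generator's
#' default effect sizes.
#'
#' @param path CSV path; defaults to the bundled file.
#' @return Data frame with columns analysis, task, target, direction, row,
#'   mean, ci_low, ci_high, probability.
#' @export
published_summaries <- function(path = system.file("extdata",
                                                   "published_summaries.csv",
                                                   package = "vbdm")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Conjugate reproduction of the published posterior rows
#'
#' For every analysis block, converts the printed prior and likelihood 95%
#' intervals to normal standard deviations, combines them by precision
#' weighting, and computes the directional posterior probability. Returns
#' the computed posterior next to the published posterior row so the
#' agreement can be inspected (and is asserted by the test suite).
#'
#' @param summaries Data frame from [published_summaries()].
#' @return Data frame, one row per block: analysis, task, target, direction,
#'   computed posterior mean/sd/ci and probability, published posterior
#'   mean/ci/probability.
#' @export
conjugate_table <- function(summaries = published_summaries()) {
  blocks <- unique(summaries[, c("analysis", "task", "target", "direction")])
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    rows <- summaries[summaries$analysis == b$analysis &
                        summaries$task == b$task &
                        summaries$target == b$target, ]
    pick <- function(r) rows[rows$row == r, ]
    prior <- normal_summary(pick("prior")$mean,
                            ci = c(pick("prior")$ci_low,
                                   pick("prior")$ci_high))
    lik <- normal_summary(pick("likelihood")$mean,
                          ci = c(pick("likelihood")$ci_low,
                                 pick("likelihood")$ci_high))
    post <- combine_normal_summaries(prior, lik)
    data.frame(
      b,
      mean = post$mean, sd = post$sd,
      ci_low = post$ci[1], ci_high = post$ci[2],
      probability = directional_probability(post, b$direction),
      published_mean = pick("posterior")$mean,
      published_ci_low = pick("posterior")$ci_low,
      published_ci_high = pick("posterior")$ci_high,
      published_probability = pick("posterior")$probability,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Three-row report block for one fitted analysis
#'
#' Formats one analysis in the published layout: rows Posterior / Prior /
#' Likelihood with mean, central 95% interval, and the directional
#' probability (whole percent) on the posterior row.
#'
#' @param prior,likelihood,posterior `vbdm_normal` summaries.
#' @param direction `"greater"` or `"less"`.
#' @param label Optional analysis label recycled down the rows.
#' @return Data frame with columns label, row, mean, ci_low, ci_high,
#'   probability.
#' @export
report_block <- function(prior, likelihood, posterior, direction,
                         label = NA_character_) {
  data.frame(
    label = label,
    row = c("posterior", "prior", "likelihood"),
    mean = c(posterior$mean, prior$mean, likelihood$mean),
    ci_low = c(posterior$ci[1], prior$ci[1], likelihood$ci[1]),
    ci_high = c(posterior$ci[2], prior$ci[2], likelihood$ci[2]),
    probability = c(round(directional_probability(posterior, direction)),
                    NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Report block from a fitted Bayesian model result
#'
#' @param result A result list from [fit_group_difference()] (uses the SUD
#'   or ND coefficient chosen by `which`) or [fit_prediction()].
#' @param prior The `vbdm_normal` prior that was used.
#' @param which For group differences, `"sud"` or `"nd"`.
#' @return Data frame as in [report_block()].
#' @export
result_report <- function(result, prior, which = NULL) {
  if (!is.null(which)) {
    dr <- result[[which]]
    lik <- result[[paste0("likelihood_", which)]]
    label <- paste(result$task, toupper(which))
  } else {
    dr <- result$predictor
    lik <- result$likelihood
    label <- paste(result$task, result$outcome)
  }
  block <- report_block(prior, lik, dr$summary, result$direction, label)
  block$probability[1] <- round(dr$probability)
  block
}
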