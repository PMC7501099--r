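#!/usr/bin/env Rscript
# One-year prediction models: standardised change in SUD/ND criteria and in
# class QFI engagement regressed on each baseline decision parameter, with
# the medium-association prior; group-interaction models for loss aversion.
#
# Output: results/predictions.csv, results/prediction_interactions.csv

suppressPackageStartupMessages(library(vbdm))
dir.create("results", showWarnings = FALSE)

cohort <- read_cohort_csv("results/cohort.csv")
priors <- default_priors("prediction")
mc <- mcmc_config(seed = 20260920L)

blocks <- list()
cat("== Predictions (posterior mean | directional probability) ==\n")
for (task in vbdm_tasks()) {
  for (out in c("sud_criteria", "nd_criteria", "qfi_sud", "qfi_nd")) {
    res <- fit_prediction(cohort, task, out, priors = priors, mcmc = mc)
    blocks[[paste(task, out)]] <- result_report(res, priors[[task]]$prior)
    cat(sprintf("  %-13s -> %-12s %+0.2f  (%2.0f%%)\n", task, out,
                res$predictor$summary$mean, res$predictor$probability))
  }
}
write.csv(do.call(rbind, blocks), "results/predictions.csv",
          row.names = FALSE)

cat("\n== Group-interaction models (loss aversion) ==\n")
rows <- list()
for (out in c("sud_criteria", "nd_criteria")) {
  res <- fit_prediction(cohort, "loss_aversion", out, priors = priors,
                        mcmc = mc, interaction = TRUE)
  rows[[out]] <- data.frame(
    outcome = out,
    interaction_sud_mean = res$interaction_sud$summary$mean,
    interaction_sud_pct = res$interaction_sud$probability,
    interaction_nd_mean = res$interaction_nd$summary$mean,
    interaction_nd_pct = res$interaction_nd$probability
  )
  cat(sprintf("  %-13s SUD x pred %2.0f%%   ND x pred %2.0f%%\n", out,
              res$interaction_sud$probability, res$interaction_nd$probability))
}
write.csv(do.call(rbind, rows), "results/prediction_interactions.csv",
          row.names = FALSE)
cat("\nWith the default generator (no group-specific associations) the\n")
cat("interaction probabilities hover near the prior-implied level.\n")
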