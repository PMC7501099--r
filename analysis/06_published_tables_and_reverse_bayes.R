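#!/usr/bin/env Rscript
# Deterministic checks against the bundled published summary rows: the
# precision-weighted reproduction of the posterior column, and the
# reverse-Bayes prior-relaxation traces for the delay-discounting contrasts.
#
# Output: results/conjugate_table.csv, results/reverse_bayes.csv

suppressPackageStartupMessages(library(vbdm))
dir.create("results", showWarnings = FALSE)

ct <- conjugate_table()
write.csv(ct, "results/conjugate_table.csv", row.names = FALSE)
cat("== Conjugate reproduction of the published posterior column ==\n")
ok <- abs(ct$mean - ct$published_mean) < 0.01
cat(sprintf("  %d of %d blocks agree within 0.01", sum(ok), nrow(ct)),
    "(the remainder reflect covariate-adjusted MCMC posteriors that the\n",
    "  two-number combination cannot reproduce)\n")
print(ct[ok, c("analysis", "task", "target", "mean", "published_mean",
               "probability")], digits = 2, row.names = FALSE)

cat("\n== Reverse-Bayes prior relaxation (delay discounting) ==\n")
s <- published_summaries()
rows <- list()
for (target in c("SUD", "ND")) {
  lik_row <- s[s$analysis == "group_diff" & s$task == "delay" &
                 s$target == target & s$row == "likelihood", ]
  lik <- normal_summary(lik_row$mean, ci = c(lik_row$ci_low, lik_row$ci_high))
  for (anchor in c("start", "decimal")) {
    rb <- reverse_bayes(lik, prior_var = 0.02, direction = "greater",
                        threshold = 0.95, start_mean = 0.37, anchor = anchor)
    rows[[paste(target, anchor)]] <- data.frame(
      target = target, anchor = anchor, passed = rb$passed,
      most_pessimistic_mean = rb$mean)
    cat(sprintf("  %s (%s anchor): most pessimistic passing prior mean = %s\n",
                target, anchor,
                ifelse(is.na(rb$mean), "none", sprintf("%.2f", rb$mean))))
  }
}
write.csv(do.call(rbind, rows), "results/reverse_bayes.csv",
          row.names = FALSE)
cat("\nUnder the two-number combination the evidence is less robust to the\n")
cat("prior than the covariate-adjusted analysis: the walk stops earlier.\n")
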