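#!/usr/bin/env Rscript
# Build the severity outcomes: per-behaviour QFIs, the two-stage long-format
# standardisation, one-year change scores, and the Tukey outlier masks.
#
# Output: results/severity_long.csv, results/change_outcomes.csv

suppressPackageStartupMessages(library(vbdm))
dir.create("results", showWarnings = FALSE)

cohort <- read_cohort_csv("results/cohort.csv")
masked <- attrit(cohort)

long <- severity_long(masked)
write.csv(long, "results/severity_long.csv", row.names = FALSE)
cat("== Long severity records ==\n")
cat("  rows:", nrow(long), " (participants x waves x behaviours)\n")
cat("  QFI medians by behaviour and group (baseline):\n")
bl <- long[long$wave == "baseline", ]
print(round(tapply(bl$qfi, list(bl$behaviour, bl$group), median), 1))

scores <- class_qfi_scores(long)
cat("\nClass QFI z-scores: pooled mean/sd per class:\n")
print(round(do.call(rbind, lapply(split(scores$qfi_z, scores$class),
                                  function(z) c(mean = mean(z), sd = sd(z)))), 6))

chg <- list(
  sud_criteria = suppressWarnings(
    build_change_outcome(masked, "sud_criteria_bl", "sud_criteria_fu")),
  nd_criteria = suppressWarnings(
    build_change_outcome(masked, "nd_criteria_bl", "nd_criteria_fu"))
)
out <- do.call(rbind, Map(function(d, nm) cbind(outcome = nm, d),
                          chg, names(chg)))
write.csv(out, "results/change_outcomes.csv", row.names = FALSE)
cat("\n== Change outcomes ==\n")
for (nm in names(chg)) {
  cat(sprintf("  %-13s n = %d  mean raw change = %+.2f criteria\n",
              nm, nrow(chg[[nm]]), mean(chg[[nm]]$change)))
}

cat("\n== Tukey 1.5 IQR masks on the decision parameters ==\n")
for (task in vbdm_tasks()) {
  keep <- tukey_filter(cohort[[task_zcol(task)]])
  cat(sprintf("  %-13s excluded: %d of %d\n", task, sum(!keep), length(keep)))
}
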