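#!/usr/bin/env Rscript
# Generate the synthetic three-group cohort (SUD / ND / controls) with the
# default, likelihood-anchored effect sizes, and summarise its structure.
#
# Output: results/cohort.csv, results/cohort_summary.csv

suppressPackageStartupMessages(library(vbdm))
dir.create("results", showWarnings = FALSE)

config <- cohort_config(seed = 20260920L)
cohort <- generate_cohort(config)
write_cohort_csv(cohort, "results/cohort.csv")

cat("== Cohort ==\n")
cat("  n =", nrow(cohort), " retained at follow-up:", sum(cohort$retained),
    sprintf("(%.1f%%)\n", 100 * mean(cohort$retained)))
print(table(cohort$group))

summ <- do.call(rbind, lapply(split(cohort, cohort$group), function(g) {
  data.frame(
    group = g$group[1], n = nrow(g),
    age_mean = round(mean(g$age), 1),
    pct_female = round(100 * mean(g$female), 1),
    sud_criteria_med = median(g$sud_criteria_bl),
    nd_criteria_med = median(g$nd_criteria_bl),
    z_logk_delay_mean = round(mean(g$z_logk_delay), 2),
    z_loglambda_mean = round(mean(g$z_loglambda), 2)
  )
}))
print(summ, row.names = FALSE)
write.csv(summ, "results/cohort_summary.csv", row.names = FALSE)
cat("\nCase groups sit at their calibration medians (SUD criteria ~3,",
    "ND criteria ~4); decision parameters carry the configured",
    "group-minus-control shifts.\n")
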