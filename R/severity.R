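#' Frequency categories and their per-week maxima
#'
#' The interview records engagement frequency in five ordered categories;
#' the quantity-frequency index (QFI) multiplies the quantity per occasion
#' by the category maximum expressed per week: almost daily = 7, 3-4 times
#' per week = 4, 1-2 times per week = 2, 1-3 times per month = 0.75,
#' less often than monthly = 0.25. The weekly scaling makes the index
#' directly comparable to per-week consumption summaries.
#'
#' @return Named numeric vector, strictly decreasing across the category
#'   order.
#' @export
frequency_week_max <- function() {
  c(almost_daily = 7, `3-4_per_week` = 4, `1-2_per_week` = 2,
    `1-3_per_month` = 0.75, less_than_monthly = 0.25)
}

#' Quantity-frequency index
#'
#' `qfi = per-week category maximum x quantity per occasion`; units per week
#' (cigarettes, grams of ethanol, or hours).
#'
#' @param quantity Units per occasion (>= 0).
#' @param frequency Character vector of frequency-category labels.
#' @param week_max Optional alternative category-to-multiplier mapping.
#' @return QFI in units per week.
#' @export
compute_qfi <- function(quantity, frequency, week_max = frequency_week_max()) {
  if (any(quantity < 0)) stop("`quantity` must be non-negative")
  unknown <- setdiff(unique(frequency), names(week_max))
  if (length(unknown)) {
    stop("unknown frequency category: ", paste(unknown, collapse = ", "))
  }
  unname(week_max[frequency] * quantity)
}

#' z-standardise a column (sample sd)
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return z-scores with mean 0 and sample sd 1.
#' @export
standardize_long <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2 || stats::sd(x[ok]) == 0) {
    stop("cannot standardise: fewer than two distinct values")
  }
  (x - mean(x[ok])) / stats::sd(x[ok])
}

#' Long-format severity records from a cohort
#'
#' One row per participant x wave x behaviour with quantity, frequency
#' category, per-behaviour criteria count, and the computed QFI.
#'
#' @param cohort A `vbdm_cohort` data frame.
#' @return Long data frame: id, group, wave, behaviour, class, quantity,
#'   frequency, criteria, qfi.
#' @export
severity_long <- function(cohort) {
  cat_tab <- behaviour_catalogue()
  out <- list()
  for (beh in names(cat_tab)) {
    for (w in c("bl", "fu")) {
      q <- cohort[[paste0("q_", beh, "_", w)]]
      f <- cohort[[paste0("f_", beh, "_", w)]]
      keep <- !is.na(q) & !is.na(f)
      out[[paste(beh, w)]] <- data.frame(
        id = cohort$id[keep], group = as.character(cohort$group)[keep],
        wave = if (w == "bl") "baseline" else "follow_up",
        behaviour = beh, class = cat_tab[[beh]]$class,
        quantity = q[keep], frequency = f[keep],
        criteria = cohort[[paste0("crit_", beh, "_", w)]][keep],
        qfi = compute_qfi(q[keep], f[keep]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Class-level QFI z-scores in long format
#'
#' Implements the two-stage standardisation of engagement: each behaviour's
#' QFI column is z-standardised pooled over both waves (long format, so
#' baseline and follow-up are comparable), the z-scores are summed per
#' participant and wave separately for the substance-related and
#' non-substance-related classes, and each class sum is z-standardised
#' again (pooled over waves).
#'
#' @param long Long severity records from [severity_long()].
#' @return Data frame: id, wave, class, qfi_z.
#' @export
class_qfi_scores <- function(long) {
  long$qfi_z <- stats::ave(long$qfi, long$behaviour, FUN = standardize_long)
  sums <- stats::aggregate(qfi_z ~ id + wave + class, data = long, FUN = sum)
  sums$qfi_z <- stats::ave(sums$qfi_z, sums$class, FUN = standardize_long)
  sums[order(sums$class, sums$id, sums$wave), c("id", "wave", "class",
                                                "qfi_z")]
}

#' Per-participant standardised one-year change outcome
#'
#' Builds the change-score outcome used by the prediction models:
#' `change = follow-up - baseline`, z-standardised across the analysis
#' sample, with the baseline value carried as a covariate (the
#' difference-of-difference adjustment against regression to the mean).
#' Participants without a follow-up value (non-retained, or missing) are
#' dropped with a warning.
#'
#' @param d Data frame containing the id and the two wave columns.
#' @param baseline,followup Column names of the two waves.
#' @param id Column name of the participant id.
#' @return Data frame: id, baseline, change, change_z.
#' @export
build_change_outcome <- function(d, baseline, followup, id = "id") {
  keep <- !is.na(d[[followup]]) & !is.na(d[[baseline]])
  if (any(!keep)) {
    warning(sum(!keep), " participant(s) dropped: missing wave value")
  }
  d <- d[keep, , drop = FALSE]
  change <- d[[followup]] - d[[baseline]]
  if (stats::sd(change) == 0) {
    stop("degenerate change outcome: no variation between waves")
  }
  data.frame(id = d[[id]], baseline = d[[baseline]], change = change,
             change_z = standardize_long(change), stringsAsFactors = FALSE)
}

#' Tukey-fence (1.5 IQR) inclusion mask
#'
#' Box-plot whisker rule: a value is excluded when it falls below
#' `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, with quartiles computed by
#' linear-interpolation quantiles (type 7). With zero IQR the fences
#' collapse onto the quartiles and only values outside them are excluded.
#'
#' @param x Numeric vector of at least 4 values.
#' @return Logical mask, `FALSE` where the value is an outlier.
#' @export
tukey_filter <- function(x) {
  if (length(x) < 4) stop("need at least 4 values for Tukey fences")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr
}
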