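#' Configuration for the synthetic three-group cohort
#'
#' Defaults emulate the study conditions of a prospective-longitudinal
#' community sample of young adults: groups of 100 (SUD), 118 (ND), and 120
#' (controls); one-year retention of 92%; standardised group-minus-control
#' shifts in the four decision parameters and standardised
#' parameter-to-outcome prediction coefficients set to the reported
#' likelihood (data-only) effect sizes; demographic distributions anchored
#' to the baseline sample description.
#'
#' @param group_sizes Named vector `c(SUD =, ND =, control =)`.
#' @param retention One-year retention probability in (0, 1].
#' @param group_shift Matrix (task x group) of standardised decision-
#'   parameter shifts relative to controls; see [default_group_shift()].
#' @param assoc Matrix (task x outcome) of standardised prediction
#'   coefficients onto one-year severity change; see [default_assoc()].
#' @param noise_sd Residual sd of the standardised change outcomes; by
#'   default chosen per outcome so the change score has unit variance,
#'   `sqrt(1 - sum(assoc^2))`.
#' @param covariate_effects Named vector of standardised effects of the
#'   demographic covariates on the change outcomes (default all zero; the
#'   adjustment machinery is exercised but unbiased).
#' @param criteria_scale Criteria moved per 1 SD of latent change (default
#'   2).
#' @param seed Integer seed.
#' @return A `vbdm_cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(SUD = 100L, ND = 118L,
                                          control = 120L),
                          retention = 0.92,
                          group_shift = default_group_shift(),
                          assoc = default_assoc(),
                          noise_sd = NULL,
                          covariate_effects = c(age = 0, female = 0, iq = 0,
                                                income_low = 0, abitur = 0),
                          criteria_scale = 2,
                          seed = 1L) {
  stopifnot(all(group_sizes > 0), retention > 0, retention <= 1)
  stopifnot(all(rownames(group_shift) == vbdm_tasks()),
            all(rownames(assoc) == vbdm_tasks()))
  if (is.null(noise_sd)) {
    noise_sd <- sqrt(pmax(1 - colSums(assoc^2), 0.1))
  }
  structure(
    list(group_sizes = group_sizes, retention = retention,
         group_shift = group_shift, assoc = assoc, noise_sd = noise_sd,
         covariate_effects = covariate_effects,
         criteria_scale = criteria_scale, seed = as.integer(seed)),
    class = "vbdm_cohort_config"
  )
}

#' Task labels of the four-facet battery
#'
#' @return Character vector of the four task labels, in battery order.
#' @export
vbdm_tasks <- function() c("delay", "prob_gain", "prob_loss", "loss_aversion")

#' Default standardised group-minus-control parameter shifts
#'
#' Rows are tasks, columns SUD and ND; values are the reported likelihood
#' means of the group-difference analyses (delay 0.24/0.08, probability
#' discounting for gains -0.09/-0.06, for losses -0.27/-0.21, loss aversion
#' 0.09/0.12).
#'
#' @return A 4 x 2 matrix.
#' @export
default_group_shift <- function() {
  matrix(c(0.24, 0.08,
           -0.09, -0.06,
           -0.27, -0.21,
           0.09, 0.12),
         nrow = 4, byrow = TRUE,
         dimnames = list(vbdm_tasks(), c("SUD", "ND")))
}

#' Default standardised prediction coefficients
#'
#' Rows are tasks, columns the four one-year change outcomes; values are the
#' reported likelihood means of the prediction analyses.
#'
#' @return A 4 x 4 matrix.
#' @export
default_assoc <- function() {
  matrix(c(0.10, 0.00, 0.11, 0.05,
           -0.02, -0.03, 0.00, 0.03,
           0.05, -0.06, 0.02, 0.02,
           -0.13, -0.07, -0.04, -0.02),
         nrow = 4, byrow = TRUE,
         dimnames = list(vbdm_tasks(),
                         c("sud_criteria", "nd_criteria",
                           "qfi_sud", "qfi_nd")))
}

# Behaviour catalogue: class membership, engagement probability, modal
# frequency category and median quantity per occasion, per group. Anchored
# to the reported per-group QFI medians (cigarettes and grams of ethanol per
# week; hours per week for the non-substance behaviours).
behaviour_catalogue <- function() {
  list(
    tobacco  = list(class = "sud", unit = "cigarettes",
                    p_engage = c(SUD = 0.55, ND = 0.25, control = 0.25),
                    freq = c(SUD = "almost_daily", ND = "1-2_per_week",
                             control = "1-2_per_week"),
                    q_med = c(SUD = 2, ND = 1, control = 1)),
    alcohol  = list(class = "sud", unit = "g_ethanol",
                    p_engage = c(SUD = 0.95, ND = 0.85, control = 0.85),
                    freq = c(SUD = "3-4_per_week", ND = "1-2_per_week",
                             control = "1-2_per_week"),
                    q_med = c(SUD = 18, ND = 9, control = 11)),
    internet = list(class = "nd", unit = "hours",
                    p_engage = c(SUD = 0.45, ND = 0.95, control = 0.45),
                    freq = c(SUD = "1-2_per_week", ND = "almost_daily",
                             control = "1-2_per_week"),
                    q_med = c(SUD = 1, ND = 2, control = 1)),
    gaming   = list(class = "nd", unit = "hours",
                    p_engage = c(SUD = 0.30, ND = 0.45, control = 0.30),
                    freq = c(SUD = "1-2_per_week", ND = "1-2_per_week",
                             control = "1-2_per_week"),
                    q_med = c(SUD = 1, ND = 1.5, control = 1)),
    gambling = list(class = "nd", unit = "hours",
                    p_engage = c(SUD = 0.10, ND = 0.10, control = 0.05),
                    freq = c(SUD = "1-3_per_month", ND = "1-3_per_month",
                             control = "1-3_per_month"),
                    q_med = c(SUD = 1, ND = 1, control = 1)),
    shopping = list(class = "nd", unit = "hours",
                    p_engage = c(SUD = 0.15, ND = 0.15, control = 0.15),
                    freq = c(SUD = "1-3_per_month", ND = "1-3_per_month",
                             control = "1-3_per_month"),
                    q_med = c(SUD = 1, ND = 1, control = 1))
  )
}

# Sample a frequency category near the modal one (60% modal, 20% each
# neighbour, clipped at the ends of the ordered category list).
sample_frequency <- function(modal, n) {
  cats <- names(frequency_week_max())
  j <- match(modal, cats)
  idx <- j + sample(c(-1L, 0L, 1L), n, replace = TRUE,
                    prob = c(0.2, 0.6, 0.2))
  cats[pmin(pmax(idx, 1L), length(cats))]
}

# Split a class-level criteria sum across two behaviours given a subtype
# label; per-behaviour counts are capped at 11.
split_two <- function(total, first_share) {
  a <- pmin(round(total * first_share), 11L)
  b <- pmin(total - a, 11L)
  c(a, b)
}

#' Generate the synthetic cohort
#'
#' One row per participant: group, demographics, standardised true decision
#' parameters, baseline and follow-up DSM-5 criterion counts (class sums and
#' per-behaviour counts), per-behaviour quantity and frequency at both
#' waves, and a retention flag. Group diagnostic invariants hold by
#' construction: case groups have >= 2 criteria on their own class and <= 1
#' on the other; controls <= 1 on both.
#'
#' One-year change is generated on the latent standardised scale,
#' `z(change) = sum(assoc * z(parameter)) + covariate terms + noise`, and
#' mapped to integer criterion counts by scaling (`criteria_scale` per SD),
#' rounding, adding the case-group drift, and clipping at zero and the class
#' cap. Quantities follow a log-normal anchored at the per-group medians,
#' with follow-up quantities coupled to the latent QFI change.
#'
#' @param config A `vbdm_cohort_config`.
#' @return A data frame of participants (`vbdm_cohort`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "vbdm_cohort_config"))
  set.seed(config$seed)
  sizes <- config$group_sizes
  n <- sum(sizes)
  group <- factor(rep(names(sizes), sizes),
                  levels = c("control", "SUD", "ND"))
  d <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    group = group,
    age = round(pmin(pmax(stats::rnorm(n, 21.8, 1.7), 19), 27), 1),
    female = stats::rbinom(n, 1, c(control = 0.633, SUD = 0.53,
                                   ND = 0.593)[as.character(group)]),
    iq = round(stats::rnorm(n, 104.3, 9.8)),
    income_low = stats::rbinom(n, 1, 0.76),
    abitur = stats::rbinom(n, 1, c(control = 0.82, SUD = 0.69,
                                   ND = 0.72)[as.character(group)]),
    stringsAsFactors = FALSE
  )

  # Standardised true decision parameters: N(group shift, 1), independent
  # across tasks (no reported cross-parameter correlations).
  shift <- cbind(config$group_shift, control = c(0, 0, 0, 0))
  zcols <- c(delay = "z_logk_delay", prob_gain = "z_logk_pgain",
             prob_loss = "z_logk_ploss", loss_aversion = "z_loglambda")
  for (task in vbdm_tasks()) {
    d[[zcols[[task]]]] <- stats::rnorm(n) + shift[task, as.character(group)]
  }

  # Baseline class criteria sums: latent-Gaussian construction anchored at
  # the case-group medians (3 for SUD sums in the SUD group, 4 for ND sums
  # in the ND group); non-case classes at the 0/1 sub-diagnostic level.
  is_sud <- group == "SUD"; is_nd <- group == "ND"
  d$sud_criteria_bl <- stats::rbinom(n, 1, 0.25)
  d$sud_criteria_bl[is_sud] <-
    pmin(2L + pmax(0L, round(stats::rnorm(sum(is_sud), 0.8, 1.5))), 13L)
  d$nd_criteria_bl <- stats::rbinom(n, 1, 0.25)
  d$nd_criteria_bl[is_nd] <-
    pmin(2L + pmax(0L, round(stats::rnorm(sum(is_nd), 1.8, 2.0))), 15L)

  # Latent standardised one-year change per outcome.
  zmat <- as.matrix(d[, zcols])
  covmat <- as.matrix(d[, names(config$covariate_effects)])
  covmat <- scale(covmat)
  covmat[is.nan(covmat)] <- 0
  chg <- matrix(NA_real_, n, ncol(config$assoc),
                dimnames = list(NULL, colnames(config$assoc)))
  for (out in colnames(config$assoc)) {
    chg[, out] <- zmat %*% config$assoc[, out] +
      covmat %*% config$covariate_effects +
      stats::rnorm(n, 0, config$noise_sd[[out]])
  }
  d$chg_sud_criteria_z <- chg[, "sud_criteria"]
  d$chg_nd_criteria_z <- chg[, "nd_criteria"]
  d$chg_qfi_sud_z <- chg[, "qfi_sud"]
  d$chg_qfi_nd_z <- chg[, "qfi_nd"]

  # Follow-up class sums: baseline + scaled rounded latent change + case-
  # group drift (criteria decline over the year in the case groups), clipped
  # to the observed class ranges.
  sc <- config$criteria_scale
  d$sud_criteria_fu <- pmin(pmax(
    d$sud_criteria_bl +
      round(sc * chg[, "sud_criteria"] + ifelse(is_sud, -1, 0)), 0L), 13L)
  d$nd_criteria_fu <- pmin(pmax(
    d$nd_criteria_bl +
      round(sc * chg[, "nd_criteria"] + ifelse(is_nd, -2, 0)), 0L), 15L)

  # Per-behaviour criteria split by disorder subtype.
  sud_sub <- sample(c("alcohol", "tobacco", "both"), n, replace = TRUE,
                    prob = c(0.45, 0.39, 0.16))
  nd_sub <- sample(c("internet", "gaming", "both", "gambling"), n,
                   replace = TRUE, prob = c(0.70, 0.14, 0.15, 0.01))
  sud_share <- ifelse(sud_sub == "alcohol", 1,
                      ifelse(sud_sub == "tobacco", 0, 0.5))
  nd_share <- ifelse(nd_sub == "internet", 1,
                     ifelse(nd_sub == "both", 0.5, 0))
  for (w in c("bl", "fu")) {
    s <- d[[paste0("sud_criteria_", w)]]
    d[[paste0("crit_alcohol_", w)]] <- pmin(round(s * sud_share), 11L)
    d[[paste0("crit_tobacco_", w)]] <-
      pmin(s - d[[paste0("crit_alcohol_", w)]], 11L)
    nsum <- d[[paste0("nd_criteria_", w)]]
    d[[paste0("crit_internet_", w)]] <- pmin(round(nsum * nd_share), 11L)
    rest <- nsum - d[[paste0("crit_internet_", w)]]
    d[[paste0("crit_gambling_", w)]] <-
      ifelse(nd_sub == "gambling", pmin(rest, 11L), 0L)
    d[[paste0("crit_gaming_", w)]] <-
      pmin(rest - d[[paste0("crit_gambling_", w)]], 11L)
    d[[paste0("crit_shopping_", w)]] <- 0L
  }

  # Quantities and frequencies per behaviour; follow-up quantity coupled to
  # the latent class QFI change.
  cat_tab <- behaviour_catalogue()
  for (beh in names(cat_tab)) {
    info <- cat_tab[[beh]]
    engaged <- stats::rbinom(n, 1, info$p_engage[as.character(group)]) == 1
    # participants with criteria on a behaviour are engaged in it
    engaged <- engaged | d[[paste0("crit_", beh, "_bl")]] > 0
    freq_bl <- sample_frequency(info$freq[as.character(group)], n)
    freq_bl[!engaged] <- "less_than_monthly"
    q_bl <- stats::rlnorm(n, log(info$q_med[as.character(group)]), 0.5)
    q_bl[!engaged] <- 0
    zq <- if (info$class == "sud") chg[, "qfi_sud"] else chg[, "qfi_nd"]
    q_fu <- q_bl * exp(0.45 * zq + stats::rnorm(n, 0, 0.25))
    d[[paste0("q_", beh, "_bl")]] <- round(q_bl, 2)
    d[[paste0("f_", beh, "_bl")]] <- freq_bl
    d[[paste0("q_", beh, "_fu")]] <- round(q_fu, 2)
    d[[paste0("f_", beh, "_fu")]] <- freq_bl
  }

  d$retained <- stats::rbinom(n, 1, config$retention) == 1
  class(d) <- c("vbdm_cohort", "data.frame")
  d
}

#' Apply attrition: mask follow-up fields of non-retained participants
#'
#' Independent Bernoulli thinning at the configured retention rate already
#' happened in [generate_cohort()] (the `retained` flag); this masks all
#' follow-up columns of dropped participants with `NA` so they cannot leak
#' into change-score analyses. With `retention = 1` every participant is
#' kept.
#'
#' @param cohort A `vbdm_cohort` data frame.
#' @return The cohort with follow-up fields masked where `retained` is
#'   `FALSE`.
#' @export
attrit <- function(cohort) {
  fu_cols <- grep("_fu$", names(cohort), value = TRUE)
  drop <- !cohort$retained
  for (col in fu_cols) {
    cohort[[col]][drop] <- if (is.character(cohort[[col]])) NA_character_
                           else NA
  }
  cohort
}

#' Write / read a cohort as wide CSV
#'
#' @param cohort A `vbdm_cohort`.
#' @param path File path.
#' @return `read_cohort_csv()` returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$group <- factor(d$group, levels = c("control", "SUD", "ND"))
  class(d) <- c("vbdm_cohort", "data.frame")
  d
}
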