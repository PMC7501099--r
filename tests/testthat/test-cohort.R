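test_that("the default cohort matches the study layout", {
  coh <- generate_cohort(cohort_config(seed = 3))
  expect_equal(nrow(coh), 338)
  expect_equal(as.integer(table(coh$group)[c("SUD", "ND", "control")]),
               c(100L, 118L, 120L))
  expect_true(all(coh$age >= 19 & coh$age <= 27))
  expect_true(all(coh$female %in% 0:1))
})

test_that("diagnostic group invariants hold for every participant", {
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_config(seed = seed))
    sud <- coh$group == "SUD"; nd <- coh$group == "ND"
    ctl <- coh$group == "control"
    expect_true(all(coh$sud_criteria_bl[sud] >= 2))
    expect_true(all(coh$nd_criteria_bl[sud] <= 1))
    expect_true(all(coh$nd_criteria_bl[nd] >= 2))
    expect_true(all(coh$sud_criteria_bl[nd] <= 1))
    expect_true(all(coh$sud_criteria_bl[ctl] <= 1))
    expect_true(all(coh$nd_criteria_bl[ctl] <= 1))
    expect_true(all(coh$sud_criteria_fu >= 0 & coh$nd_criteria_fu >= 0))
    crit_cols <- grep("^crit_", names(coh), value = TRUE)
    expect_true(all(as.matrix(coh[, crit_cols]) <= 11))
    expect_true(all(as.matrix(coh[, crit_cols]) >= 0))
  }
})

test_that("baseline severity medians sit at the calibration anchors", {
  sud_med <- nd_med <- numeric(10)
  for (seed in 1:10) {
    coh <- generate_cohort(cohort_config(seed = seed))
    sud_med[seed] <- median(coh$sud_criteria_bl[coh$group == "SUD"])
    nd_med[seed] <- median(coh$nd_criteria_bl[coh$group == "ND"])
  }
  expect_equal(median(sud_med), 3)
  expect_equal(median(nd_med), 4)
})

test_that("cohorts are seed-deterministic", {
  c1 <- generate_cohort(cohort_config(seed = 17))
  c2 <- generate_cohort(cohort_config(seed = 17))
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(seed = 18))
  expect_false(identical(c1$z_logk_delay, c3$z_logk_delay))
})

test_that("retention behaves binomially and attrition masks follow-up", {
  cfg <- cohort_config(retention = 1, seed = 2)
  expect_true(all(generate_cohort(cfg)$retained))

  kept <- sapply(1:20, function(s) {
    sum(generate_cohort(cohort_config(seed = s))$retained)
  })
  # mean of 20 draws from Binomial(338, 0.92): well inside the 99% band
  se <- sqrt(338 * 0.92 * 0.08 / 20)
  expect_lt(abs(mean(kept) - 338 * 0.92), 3 * se)

  coh <- generate_cohort(cohort_config(seed = 4))
  masked <- attrit(coh)
  dropped <- !masked$retained
  expect_true(any(dropped))
  expect_true(all(is.na(masked$sud_criteria_fu[dropped])))
  expect_true(all(is.na(masked$q_alcohol_fu[dropped])))
  # non-retained participants are excluded from change outcomes downstream
  chg <- suppressWarnings(
    build_change_outcome(masked, "sud_criteria_bl", "sud_criteria_fu"))
  expect_equal(nrow(chg), sum(masked$retained))
})

test_that("a null configuration yields null fitted effects", {
  cfg0 <- function(seed) {
    gs <- default_group_shift(); gs[] <- 0
    as0 <- default_assoc(); as0[] <- 0
    cohort_config(group_shift = gs, assoc = as0, seed = seed)
  }
  diffs <- assocs <- numeric(10)
  for (s in 1:10) {
    coh <- generate_cohort(cfg0(s))
    diffs[s] <- group_difference_likelihood(coh, "delay")$sud$mean
    assocs[s] <- prediction_likelihood(coh, "delay", "sud_criteria")$mean
  }
  expect_lt(abs(mean(diffs)), 0.1)
  expect_lt(abs(mean(assocs)), 0.05)
})

test_that("doubling the generating association roughly doubles the fit", {
  fit_at <- function(mult) {
    mean(sapply(1:10, function(s) {
      as1 <- default_assoc(); as1[] <- 0
      as1["delay", "sud_criteria"] <- 0.1 * mult
      coh <- generate_cohort(cohort_config(assoc = as1, seed = s))
      prediction_likelihood(coh, "delay", "sud_criteria")$mean
    }))
  }
  b1 <- fit_at(1); b2 <- fit_at(2)
  expect_gt(b2, b1)
  expect_equal(b2 / b1, 2, tolerance = 0.4)
})

test_that("cohorts round-trip through wide CSV", {
  coh <- generate_cohort(cohort_config(seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back$sud_criteria_bl, coh$sud_criteria_bl)
  expect_equal(back$z_logk_delay, coh$z_logk_delay, tolerance = 1e-9)
  expect_equal(levels(back$group), levels(coh$group))
  unlink(path)
})
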