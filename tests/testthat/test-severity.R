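test_that("the QFI multiplies quantity by the weekly category maximum", {
  expect_equal(compute_qfi(0, "almost_daily"), 0)
  expect_equal(compute_qfi(2, "almost_daily"), 14)
  expect_equal(compute_qfi(12, "3-4_per_week"), 48)
  expect_error(compute_qfi(1, "sometimes"), "unknown frequency")
  expect_error(compute_qfi(-1, "almost_daily"), "non-negative")
  # linear in quantity, monotone in category
  expect_equal(compute_qfi(6, "1-2_per_week"), 3 * compute_qfi(2, "1-2_per_week"))
  wk <- frequency_week_max()
  expect_true(all(diff(wk) < 0))
  expect_true(all(diff(compute_qfi(rep(2, 5), names(wk))) < 0))
})

test_that("long-format z-standardisation uses the sample sd", {
  z <- standardize_long(c(0, 10))
  expect_equal(z, c(-0.7071068, 0.7071068), tolerance = 1e-6)
  x <- rnorm(50, 3, 7)
  z <- standardize_long(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  # idempotent on already-standardised input
  expect_equal(standardize_long(z), z, tolerance = 1e-10)
  # z-scores stay attached to their positions under permutation
  perm <- sample(50)
  expect_equal(standardize_long(x[perm]), z[perm], tolerance = 1e-10)
  expect_error(standardize_long(rep(2, 5)), "two distinct")
})

test_that("class QFI scores follow the two-stage standardisation", {
  coh <- generate_cohort(cohort_config(seed = 21))
  long <- severity_long(coh)
  expect_true(all(long$qfi >= 0))
  expect_equal(sort(unique(long$wave)), c("baseline", "follow_up"))
  scores <- class_qfi_scores(long)
  for (cls in c("sud", "nd")) {
    z <- scores$qfi_z[scores$class == cls]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
  # two rows (waves) per participant per class
  expect_equal(nrow(scores), 2 * 2 * nrow(coh))
})

test_that("change outcomes standardise follow-up minus baseline", {
  d <- data.frame(id = c("a", "b", "c", "d"),
                  bl = c(3, 0, 1, 2), fu = c(5, 0, 1, 2))
  chg <- build_change_outcome(d, "bl", "fu")
  # changes are (2, 0, 0, 0): mean 0.5, sample sd 1; participant a at z = 1.5
  expect_equal(chg$change, c(2, 0, 0, 0))
  expect_equal(chg$change_z[1], 1.5)
  expect_equal(chg$baseline, d$bl)

  d$fu[2] <- NA
  expect_warning(chg2 <- build_change_outcome(d, "bl", "fu"), "dropped")
  expect_equal(nrow(chg2), 3)

  d0 <- data.frame(id = letters[1:4], bl = 1:4, fu = 1:4)
  expect_error(build_change_outcome(d0, "bl", "fu"), "degenerate")
})

test_that("Tukey fences match a brute-force computation", {
  expect_equal(tukey_filter(c(1, 2, 3, 4)), rep(TRUE, 4))
  expect_equal(tukey_filter(c(1, 2, 3, 100)), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(tukey_filter(rep(5, 6)), rep(TRUE, 6))
  expect_error(tukey_filter(c(1, 2, 3)), "at least 4")
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(4:30, 1)) * sample(c(1, 10), 1)
    q1 <- quantile(x, 0.25, type = 7, names = FALSE)
    q3 <- quantile(x, 0.75, type = 7, names = FALSE)
    brute <- x >= q1 - 1.5 * (q3 - q1) & x <= q3 + 1.5 * (q3 - q1)
    expect_equal(tukey_filter(x), brute)
  }
})
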