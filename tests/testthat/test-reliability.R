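test_that("slice_last_strides keeps the final n values in order", {
  expect_identical(slice_last_strides(1:10, 3), 8:10)
  x <- rnorm(20)
  expect_identical(slice_last_strides(x, 20), x)
  expect_error(slice_last_strides(rnorm(100), 173))
  # data-frame method preserves labels and groups
  d <- tibble::tibble(
    subject = rep("S1", 20), day = rep(1:2, each = 10),
    trial = 1L, variable = "v", stride = rep(1:10, 2), value = 1:20
  )
  out <- slice_last_strides(d, 4)
  expect_identical(nrow(out), 8L)
  expect_identical(out$value[out$day == 1], 7:10)
})

test_that("day_average means the first k trials in trial order", {
  d <- tibble::tibble(
    subject = "S1", day = 1L, trial = 1:3, h = c(0.7, 0.8, 0.9)
  )
  expect_equal(day_average(d, 2)$h_mean, 0.75)
  expect_equal(day_average(d, 1)$h_mean, 0.7)
  expect_equal(day_average(d, 3)$h_mean, mean(c(0.7, 0.8, 0.9)))
  expect_error(day_average(d, 4))
})

test_that("icc_3k matches the aov oracle on fixed and random tables", {
  m <- cbind(c(0.70, 0.80, 0.60, 0.90), c(0.72, 0.79, 0.64, 0.88))
  expect_equal(icc_3k(m)$icc, oracle_icc_3k(m), tolerance = 1e-10)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    k <- sample(2:4, 1)
    tab <- matrix(rnorm(n * k, 0.7, 0.1), n, k) +
      rnorm(n, 0, runif(1, 0.02, 0.2))
    expect_equal(icc_3k(tab)$icc, oracle_icc_3k(tab), tolerance = 1e-10)
  }
})

test_that("consistency ICC ignores fixed day effects", {
  day1 <- c(0.70, 0.80, 0.60, 0.90, 0.75)
  expect_equal(icc_3k(cbind(day1, day1))$icc, 1)
  expect_equal(icc_3k(cbind(day1, day1 + 0.3))$icc, 1)
})

test_that("icc_3k confidence interval brackets the estimate", {
  set.seed(32)
  for (i in 1:20) {
    tab <- matrix(rnorm(16, 0.7, 0.05), 8, 2) + rnorm(8, 0, 0.1)
    r <- icc_3k(tab)
    expect_lte(r$ci_low, r$icc)
    expect_lte(r$icc, r$ci_high)
  }
})

test_that("icc_3k rejects degenerate input", {
  expect_error(icc_3k(cbind(rep(0.7, 5), rep(0.7, 5))))
  expect_error(icc_3k(cbind(c(0.7, 0.8), c(0.7, 0.8)))) # < 3 subjects
  expect_error(icc_3k(matrix(0.7, 5, 1))) # single measurement
})

test_that("band thresholds are boundary-inclusive upward", {
  expect_identical(as.character(icc_band(c(0.49, 0.5, 0.749, 0.75, 0.89, 0.9))),
                   c("poor", "moderate", "moderate", "good", "good", "excellent"))
})

test_that("icc_3k accepts tidy long input", {
  d <- tibble::tibble(
    subject = rep(paste0("S", 1:4), each = 2),
    day = rep(1:2, 4),
    h_mean = c(0.70, 0.72, 0.80, 0.79, 0.60, 0.64, 0.90, 0.88)
  )
  m <- matrix(d$h_mean, 4, 2, byrow = TRUE)
  expect_equal(icc_3k(d)$icc, icc_3k(m)$icc, tolerance = 1e-12)
})

test_that("reliability_grid has the full shape contract and flags bad cells", {
  coh <- generate_cohort(
    n_subjects = 6, groups = "g", trials_per_day = 3, strides_per_trial = 40,
    between_subject_sd = 0.08, between_day_sd = 0.02, between_trial_sd = 0.04,
    seed = 33
  )
  g <- reliability_grid(coh, method = "dfa", stride_counts = c(32, 40),
                        trials = 1:3)
  expect_identical(nrow(g), 6L) # 2 stride counts x 3 trial counts
  expect_setequal(g$trials_used, 1:3)
  expect_true(all(c("icc", "ci_low", "ci_high", "band") %in% names(g)))
  # degenerate cohort: zero between-subject variance flagged as NA, not dropped
  coh0 <- generate_cohort(
    n_subjects = 5, groups = "g", trials_per_day = 1, strides_per_trial = 24,
    between_subject_sd = 0, between_day_sd = 0, between_trial_sd = 0, seed = 34
  )
  g0 <- reliability_grid(coh0, method = "true", stride_counts = 24, trials = 1)
  expect_identical(nrow(g0), 1L)
  expect_true(is.na(g0$icc))
})

test_that("true-H bypass recovers the designed between-day reliability", {
  # components chosen for a design ICC of 0.9 with 2 trials averaged
  sb <- 0.09
  sw <- sqrt(2 * sb^2 * (1 / 0.9 - 1))
  target <- expected_day_icc(sb, sw, 0, k_trials = 2)
  expect_equal(target, 0.9, tolerance = 1e-12)
  coh <- generate_cohort(
    n_subjects = 40, groups = "g", trials_per_day = 2, strides_per_trial = 16,
    between_subject_sd = sb, between_day_sd = sw, between_trial_sd = 0,
    seed = 35
  )
  cell <- reliability_grid(coh, method = "true", stride_counts = 16, trials = 2)
  expect_gt(cell$icc, cell$ci_low)
  expect_true(cell$ci_low <= 0.9 && 0.9 <= cell$ci_high)
})

test_that("estimator noise does not inflate reliability on average", {
  set.seed(36)
  diff_icc <- replicate(5, {
    coh <- generate_cohort(
      n_subjects = 12, groups = "g", trials_per_day = 2, strides_per_trial = 64,
      between_subject_sd = 0.09, between_day_sd = 0.03, between_trial_sd = 0.03,
      seed = sample.int(1e6, 1)
    )
    noisy <- reliability_grid(coh, method = "hkp", stride_counts = 64,
                              trials = 2, seed = 1)$icc
    clean <- reliability_grid(coh, method = "true", stride_counts = 64,
                              trials = 2)$icc
    clean - noisy
  })
  expect_gt(mean(diff_icc), 0)
})
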