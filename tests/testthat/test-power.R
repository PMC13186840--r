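test_that("vectorized t-test p-values match stats::t.test", {
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1), 0.75, 0.1)
    b <- rnorm(sample(5:30, 1), 0.8, 0.15)
    pw <- hurstlab:::t_test_pvals(mean(a), var(a), length(a),
                                  mean(b), var(b), length(b), welch = TRUE)
    expect_equal(pw, t.test(a, b)$p.value, tolerance = 1e-12)
    ps <- hurstlab:::t_test_pvals(mean(a), var(a), length(a),
                                  mean(b), var(b), length(b), welch = FALSE)
    expect_equal(ps, t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("power_condition validates its inputs", {
  expect_error(power_condition(-0.1, 10))
  expect_error(power_condition(0.3, 10)) # group B mean exceeds 1
  expect_error(power_condition(0.08, 1))
  expect_s3_class(power_condition(0.08, 10), "power_condition")
})

test_that("simulate_replicate is deterministic given condition and seed", {
  cond <- power_condition(0.12, 8, n_trials = 2, series_length = 50,
                          method = "dfa", reps = 1, seed = 42)
  r1 <- simulate_replicate(cond, replicate_seed = 7)
  r2 <- simulate_replicate(cond, replicate_seed = 7)
  expect_identical(attr(r1, "p_value"), attr(r2, "p_value"))
  expect_type(as.logical(r1), "logical")
})

test_that("power equals the exact rejection proportion with binomial CI", {
  cond <- power_condition(0.12, 12, method = "true", reps = 50, seed = 43)
  res <- estimate_power(cond)
  expect_equal(res$power, res$rejections / res$reps)
  expect_true(res$ci_low <= res$power && res$power <= res$ci_high)
  res1 <- estimate_power(power_condition(0.12, 12, method = "true",
                                         reps = 1, seed = 44))
  expect_true(res1$power %in% c(0, 1))
})

test_that("the estimation-bypassed pipeline reproduces analytic power", {
  # conditions placed mid-support so that (0,1) support handling is inert
  specs <- list(
    list(d = 0.12, n = 15), list(d = 0.08, n = 30), list(d = 0.05, n = 60)
  )
  for (s in specs) {
    cond <- power_condition(s$d, s$n, method = "true", reps = 800,
                            mean_a = 0.45, seed = 45)
    res <- estimate_power(cond)
    theo <- power.t.test(n = s$n, delta = s$d, sd = 0.11)$power
    mc_se <- sqrt(theo * (1 - theo) / cond$reps)
    expect_lt(abs(res$power - theo), 3 * mc_se,
              label = sprintf("|%.3f - analytic %.3f| (d=%g n=%d)",
                              res$power, theo, s$d, s$n))
  }
})

test_that("the null bypass pipeline keeps its nominal type-I error", {
  cond <- power_condition(0, 30, method = "true", reps = 2000, seed = 46)
  res <- estimate_power(cond)
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.05) / 2000
  expect_gte(res$power, bounds[1])
  expect_lte(res$power, bounds[2])
})

test_that("power rises with group size under common random numbers", {
  cond <- power_condition(0.08, 10, method = "true", reps = 400, seed = 47)
  curve <- power_curve(cond, n_grid = seq(6, 36, by = 6))
  expect_identical(nrow(curve), 6L)
  expect_gt(cor(curve$n_per_group, curve$power), 0.9)
  # CRN keeps adjacent jitter small: no material drawdown
  expect_lt(max(-diff(curve$power)), 0.02)
})

test_that("power rises with effect size, trials averaged, and series length", {
  pow_at <- function(delta, trials, len) {
    estimate_power(power_condition(delta, 14, n_trials = trials,
                                   series_length = len, method = "dfa",
                                   reps = 200, seed = 48))$power
  }
  expect_gt(pow_at(0.12, 2, 50), pow_at(0.04, 2, 50))
  expect_gt(pow_at(0.12, 4, 50), pow_at(0.12, 1, 50))
  expect_gt(pow_at(0.12, 2, 200), pow_at(0.12, 2, 50))
})

test_that("min_n_for_power finds thresholds and signals non-attainment", {
  cond <- power_condition(0.12, 10, method = "true", reps = 500, seed = 49)
  # analytic solution: ~15 per group at 80% power for d = 0.12 / 0.11
  theo_n <- ceiling(power.t.test(power = 0.8, delta = 0.12, sd = 0.11)$n)
  res <- min_n_for_power(cond, n_grid = 8:25)
  expect_true(abs(res$min_n - theo_n) <= 2)
  expect_true(res$attained)
  # target zero: first grid point
  expect_identical(min_n_for_power(cond, n_grid = 8:10, target = 0)$min_n, 8L)
  # unattainable target: sentinel
  res2 <- min_n_for_power(cond, n_grid = 4:6, target = 0.999)
  expect_false(res2$attained)
  expect_true(is.na(res2$min_n))
  expect_identical(res2$max_n_searched, 6L)
})

test_that("power_table runs a toy grid reproducibly", {
  grid <- tidyr::expand_grid(delta_h = c(0.08, 0.12), n_per_group = c(10, 20),
                             method = "true")
  t1 <- power_table(grid, reps = 100, seed = 50)
  t2 <- power_table(grid, reps = 100, seed = 50)
  expect_identical(nrow(t1), 4L)
  expect_identical(t1$power, t2$power)
  expect_true(all(t1$seed[1:2] != t1$seed[3:4]))
})
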