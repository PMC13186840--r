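test_that("hk_log_posterior reduces to the i.i.d. closed form at H = 0.5", {
  set.seed(10)
  x <- rnorm(20)
  n <- length(x)
  closed <- -0.5 * log(n) - ((n - 1) / 2) * log(sum((x - mean(x))^2))
  expect_equal(hk_log_posterior(x, 0.5), closed, tolerance = 1e-8)
})

test_that("hk_log_posterior matches the dense-inverse oracle", {
  set.seed(11)
  for (i in 1:5) {
    x <- simulate_fgn(runif(1, 0.3, 0.9), 12)
    for (h in c(0.2, 0.5, 0.8)) {
      expect_equal(hk_log_posterior(x, h), oracle_log_posterior(x, h),
                   tolerance = 1e-8)
    }
  }
  x <- simulate_fgn(0.7, 12, seed = 3)
  expect_identical(hk_log_posterior(x, 0.8), hk_log_posterior(x, 0.8))
  expect_error(hk_log_posterior(x, 1.1))
})

test_that("the posterior peak dominates a dense grid scan", {
  x <- simulate_fgn(0.75, 64, seed = 12)
  pk <- hk_posterior_peak(x)
  hs <- seq(0.001, 0.999, length.out = 999)
  lp <- vapply(hs, function(h) hk_log_posterior(x, h), 0)
  expect_true(all(exp(lp - pk$log_peak) <= 1 + 1e-6))
  # deterministic optimizer
  pk2 <- hk_posterior_peak(x)
  expect_identical(pk$peak_h, pk2$peak_h)
})

test_that("the posterior peak is consistent for long series", {
  set.seed(13)
  peaks <- replicate(8, hk_posterior_peak(simulate_fgn(0.75, 512))$peak_h)
  expect_lt(abs(mean(peaks) - 0.75), 0.05)
})

test_that("accept-reject with a flat density accepts everything uniformly", {
  cache <- hk_grid_cache(16)
  flat <- rep(0, length(cache$h))
  s <- withr::with_seed(1400, hurstlab:::ar_sample_grid(flat, cache, 5000))
  expect_length(s, 5000)
  expect_gt(stats::ks.test(s, "punif")$p.value, 0.01)
})

test_that("accept-reject sampling is reproducible and sized correctly", {
  x <- simulate_fgn(0.75, 32, seed = 15)
  s1 <- hk_accept_reject(x, seed = 16)
  s2 <- hk_accept_reject(x, seed = 16)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_length(s1, 50)
  expect_true(all(s1 > 0 & s1 < 1))
})

test_that("accepted samples follow the grid-integrated posterior", {
  set.seed(17)
  for (H in c(0.5, 0.75, 0.9)) {
    x <- simulate_fgn(H, 64)
    cache <- hk_grid_cache(64)
    lp <- drop(hurstlab:::hk_logpost_grid(matrix(x), cache))
    s <- hurstlab:::ar_sample_grid(lp, cache, 5000)
    at <- sort(s)
    emp <- seq_along(at) / length(at)
    theo <- oracle_posterior_cdf(x, at)
    expect_lt(max(abs(emp - theo)), 0.03)
  }
})

test_that("hkp_estimate reports the median of exactly 50 samples", {
  x <- simulate_fgn(0.75, 64, seed = 18)
  est <- hkp_estimate(x, seed = 19)
  expect_length(est$samples, 50)
  expect_identical(est$point, median(est$samples))
  expect_true(est$point > 0 && est$point < 1)
  # determinism
  expect_identical(hkp_estimate(x, seed = 19)$point, est$point)
  g <- glance(est)
  expect_identical(g$h, est$point)
  expect_identical(nrow(tidy(est)), 50L)
})

test_that("the HKp estimate is invariant to affine transforms", {
  x <- simulate_fgn(0.75, 64, seed = 20)
  e1 <- hkp_estimate(x, seed = 21)$point
  e2 <- hkp_estimate(5.5 * x + 3, seed = 21)$point
  expect_lt(abs(e1 - e2), 1e-9)
})

test_that("the grid cache matches exact evaluation", {
  cache <- hk_grid_cache(64)
  # posterior values agree at grid points
  x <- simulate_fgn(0.6, 64, seed = 22)
  lp <- drop(hurstlab:::hk_logpost_grid(matrix(x), cache))
  for (i in c(40, 100, 150)) {
    expect_equal(lp[i], hk_log_posterior(x, cache$h[i]), tolerance = 1e-8)
  }
  # point estimates agree within half a grid step
  for (s in 23:25) {
    y <- simulate_fgn(0.75, 64, seed = s)
    expect_lt(abs(hkp_estimate(y, seed = s + 100)$point -
                    hkp_estimate(y, seed = s + 100, cache = cache)$point), 0.005)
  }
})

test_that("HKp recovers the generating H with small bias at length 64", {
  cache <- hk_grid_cache(64)
  set.seed(26)
  ests <- vapply(1:120, function(i) {
    hkp_estimate(simulate_fgn(0.75, 64), seed = i, cache = cache)$point
  }, 0)
  expect_lt(abs(mean(ests) - 0.75), 0.05)
})

test_that("HKp disperses less than DFA on short series", {
  set.seed(27)
  n <- 100
  cache <- hk_grid_cache(n)
  X <- vapply(1:120, function(i) simulate_fgn(0.75, n), numeric(n))
  hkp <- hurstlab:::hkp_estimate_matrix(X, cache, seed = 28)
  dfa <- hurstlab:::dfa_matrix(X)$alpha
  expect_lt(sd(hkp), sd(dfa))
})
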