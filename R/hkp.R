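# ---- exact-path linear algebra ------------------------------------------

# Upper Cholesky factor of the HK correlation matrix at a given H, with a
# small jitter retry when the factorization fails near the H -> 1 boundary.
hk_chol <- function(hurst, n) {
  R <- stats::toeplitz(hk_acf(hurst, n - 1L))
  tryCatch(chol(R), error = function(e) {
    tryCatch(chol(R + diag(1e-10, n)), error = function(e2) {
      abort(sprintf("HK correlation matrix not positive definite at H = %g.", hurst))
    })
  })
}

# Log posterior terms from an upper Cholesky factor U (R = U'U) and data x:
# quad forms x'R^-1 x, 1'R^-1 x, 1'R^-1 1 and log|R| via triangular solves.
hk_logpost_from_chol <- function(U, x) {
  n <- length(x)
  b <- backsolve(U, x, transpose = TRUE)
  a <- backsolve(U, rep(1, n), transpose = TRUE)
  logdet <- 2 * sum(log(diag(U)))
  s1 <- sum(a * a)
  sx <- sum(a * b)
  q <- sum(b * b) - sx^2 / s1
  if (q <= 0) abort("degenerate series: zero generalized residual variance.")
  -0.5 * logdet - 0.5 * log(s1) - ((n - 1) / 2) * log(q)
}

#' Unnormalized log posterior of the Hurst exponent
#'
#' Log density (up to an additive constant) of the marginal posterior of H
#' for a stationary Gaussian Hurst-Kolmogorov process with unknown mean and
#' variance under a noninformative prior:
#' \deqn{\log f(H \mid x) = -\tfrac12 \log|R| - \tfrac12 \log(1'R^{-1}1)
#'   - \tfrac{n-1}{2} \log\left(x'R^{-1}x - \frac{(1'R^{-1}x)^2}{1'R^{-1}1}\right)}
#' where `R` is the n-by-n Toeplitz correlation matrix built from [hk_acf()]
#' at `hurst`. Mean and variance are marginalized out, so the value is
#' invariant (up to a constant in H) to affine transforms of the data. All
#' work is done through a Cholesky factorization in log space.
#'
#' @param x Numeric series (length >= 8).
#' @param hurst Candidate Hurst exponent in (0, 1).
#' @return The unnormalized log posterior density (scalar).
#' @export
hk_log_posterior <- function(x, hurst) {
  assert_series(x)
  assert_scalar_prob(hurst, "hurst")
  hk_logpost_from_chol(hk_chol(hurst, length(x)), x)
}

#' Locate the posterior mode of H
#'
#' Bounded one-dimensional maximization of [hk_log_posterior()] over
#' `(lower, upper)` by golden-section / parabolic search
#' ([stats::optimize()], tolerance 1e-6), with a dense 999-point grid scan
#' as a fallback should the smooth search fail. The peak density normalizes
#' the accept-reject ratio in [hk_accept_reject()].
#'
#' @param x Numeric series.
#' @param lower,upper Search bounds, strictly inside (0, 1).
#' @return List with `peak_h` and `log_peak` (unnormalized log density).
#' @export
hk_posterior_peak <- function(x, lower = 0.001, upper = 0.999) {
  assert_series(x)
  n <- length(x)
  f <- function(h) hk_logpost_from_chol(hk_chol(h, n), x)
  opt <- tryCatch(
    optimize(f, interval = c(lower, upper), maximum = TRUE, tol = 1e-6),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    hs <- seq(lower, upper, length.out = 999L)
    lp <- vapply(hs, function(h) tryCatch(f(h), error = function(e) -Inf), 0)
    return(list(peak_h = hs[which.max(lp)], log_peak = max(lp)))
  }
  list(peak_h = opt$maximum, log_peak = opt$objective)
}

#' Accept-reject sampling of the Hurst posterior
#'
#' Draws candidate values of H from U(0, 1), accepts a candidate when an
#' independent U(0, 1) draw `u` does not exceed the posterior density at the
#' candidate divided by the peak density, and repeats until `n_samples`
#' candidates have been accepted. Acceptance ratios are computed as
#' `exp(log f - log f_peak)`, clamped to \[0, 1\]; candidates where the
#' correlation matrix cannot be factorized count as density zero.
#'
#' @param x Numeric series.
#' @param n_samples Number of accepted values required (default 50).
#' @param seed Optional integer seed for reproducibility.
#' @param peak Optional precomputed result of [hk_posterior_peak()].
#' @param max_draws Hard cap on total candidate draws before failing.
#' @return Numeric vector of `n_samples` accepted H values, in acceptance
#'   order, with attribute `n_candidates` (total candidates consumed).
#' @export
hk_accept_reject <- function(x, n_samples = 50L, seed = NULL, peak = NULL,
                             max_draws = 1e6) {
  assert_series(x)
  peak <- peak %||% hk_posterior_peak(x)
  n <- length(x)
  with_seed_(seed, {
    acc <- numeric(0)
    drawn <- 0L
    chunk <- max(64L, 4L * n_samples)
    while (length(acc) < n_samples) {
      if (drawn >= max_draws) abort("accept-reject exceeded the candidate draw cap.")
      k <- min(chunk, as.integer(max_draws - drawn))
      cand <- runif(k)
      u <- runif(k)
      lp <- vapply(cand, function(h) {
        tryCatch(hk_logpost_from_chol(hk_chol(h, n), x), error = function(e) -Inf)
      }, 0)
      ratio <- pmin(exp(lp - peak$log_peak), 1)
      acc <- c(acc, cand[u <= ratio])
      drawn <- drawn + k
    }
    out <- acc[seq_len(n_samples)]
    attr(out, "n_candidates") <- drawn
    out
  })
}

#' Bayesian Hurst-Kolmogorov estimate of the Hurst exponent
#'
#' The HKp estimator: locate the posterior peak numerically, draw 50 values
#' of H by accept-reject against the peak-normalized posterior, and report
#' the median of the accepted values as the point estimate. Because the
#' process mean and variance are marginalized out, the estimate is invariant
#' to shifting and positive rescaling of the series.
#'
#' With `cache` (see [hk_grid_cache()]) the posterior is evaluated on a
#' precomputed H grid shared across series of the same length — much faster
#' inside simulations — and candidates are snapped to the nearest grid point
#' (step 0.005), which perturbs the point estimate by at most half a step.
#'
#' @param x Numeric series (length >= 8).
#' @param n_samples Accepted posterior draws for the point estimate (50).
#' @param seed Optional integer seed.
#' @param cache Optional grid cache from [hk_grid_cache()] matching
#'   `length(x)`; `NULL` (default) evaluates the posterior exactly.
#' @return Object of class `c("hkp_estimate", "hurst_estimate")`: list with
#'   `method = "HKp"`, `point` (median of samples), `samples`, `peak_h`,
#'   `log_peak`, `n`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' x <- simulate_fgn(0.75, 64, seed = 3)
#' est <- hkp_estimate(x, seed = 4)
#' est$point
#' @export
hkp_estimate <- function(x, n_samples = 50L, seed = NULL, cache = NULL) {
  assert_series(x)
  if (!is.null(cache)) {
    if (cache$n != length(x)) abort("`cache` was built for a different series length.")
    lp <- drop(hk_logpost_grid(matrix(x, ncol = 1L), cache))
    peak_i <- which.max(lp)
    samples <- with_seed_(seed, ar_sample_grid(lp, cache, n_samples))
    peak_h <- cache$h[peak_i]
    log_peak <- lp[peak_i]
  } else {
    peak <- hk_posterior_peak(x)
    samples <- hk_accept_reject(x, n_samples = n_samples, seed = seed, peak = peak)
    peak_h <- peak$peak_h
    log_peak <- peak$log_peak
  }
  structure(
    list(
      method = "HKp",
      point = median(samples),
      samples = as.numeric(samples),
      peak_h = peak_h,
      log_peak = log_peak,
      n = length(x)
    ),
    class = c("hkp_estimate", "hurst_estimate")
  )
}

# ---- grid-cached path ----------------------------------------------------

#' Precompute a posterior evaluation grid for one series length
#'
#' Factorizes the HK correlation matrix once per grid value of H and stores
#' the pieces needed to evaluate [hk_log_posterior()] for any series of that
#' length with two triangular solves. Intended for simulation runs where
#' thousands of same-length series are estimated; the accept-reject sampler
#' then snaps candidates to the nearest grid point (default step 0.005).
#'
#' @param n Series length the cache serves.
#' @param step Grid spacing in H (default 0.005).
#' @param h_min,h_max Grid end points.
#' @return An opaque list of class `hk_grid_cache`.
#' @export
hk_grid_cache <- function(n, step = 0.005, h_min = 0.005, h_max = 0.995) {
  h <- seq(h_min, h_max, by = step)
  U <- vector("list", length(h))
  a <- matrix(0, n, length(h))
  logdet <- s1 <- numeric(length(h))
  ones <- rep(1, n)
  for (i in seq_along(h)) {
    Ui <- hk_chol(h[i], n)
    U[[i]] <- Ui
    ai <- backsolve(Ui, ones, transpose = TRUE)
    a[, i] <- ai
    logdet[i] <- 2 * sum(log(diag(Ui)))
    s1[i] <- sum(ai * ai)
  }
  structure(
    list(n = n, h = h, step = step, U = U, a = a, logdet = logdet, s1 = s1),
    class = "hk_grid_cache"
  )
}

#' @export
print.hk_grid_cache <- function(x, ...) {
  cat(sprintf("<hk_grid_cache: length %d, %d H values in [%.3f, %.3f]>\n",
              x$n, length(x$h), min(x$h), max(x$h)))
  invisible(x)
}

# Log posterior of every column of X (n x m) at every grid H.
# Returns a length(h) x m matrix.
hk_logpost_grid <- function(X, cache) {
  n <- cache$n
  m <- ncol(X)
  out <- matrix(NA_real_, length(cache$h), m)
  for (i in seq_along(cache$h)) {
    B <- backsolve(cache$U[[i]], X, transpose = TRUE)
    sx <- crossprod(cache$a[, i], B) # 1 x m
    q <- colSums(B * B) - drop(sx)^2 / cache$s1[i]
    q[q <= 0] <- NA_real_
    out[i, ] <- -0.5 * cache$logdet[i] - 0.5 * log(cache$s1[i]) -
      ((n - 1) / 2) * log(q)
  }
  out
}

# Accept-reject against a grid log posterior (one series). Candidates are
# uniform on (0,1); the log density at a candidate is linearly interpolated
# between the two bracketing grid points (flat beyond the grid ends), so
# acceptance decisions track the exact posterior to O(step^2).
ar_sample_grid <- function(lp, cache, n_samples, max_draws = 1e6) {
  lp[is.na(lp)] <- -Inf
  lpmax <- max(lp)
  if (!is.finite(lpmax)) abort("posterior density is zero everywhere on the grid.")
  ng <- length(cache$h)
  # parabolic refinement of the peak: the continuous maximum sits slightly
  # above the best grid value, and the acceptance ratio must be normalized
  # by the true peak for grid and exact modes to take identical decisions
  im <- which.max(lp)
  if (im > 1L && im < ng && is.finite(lp[im - 1L]) && is.finite(lp[im + 1L])) {
    d2 <- lp[im - 1L] - 2 * lp[im] + lp[im + 1L]
    if (d2 < 0) {
      delta <- 0.5 * (lp[im - 1L] - lp[im + 1L]) / d2
      lpmax <- lp[im] - 0.25 * (lp[im - 1L] - lp[im + 1L]) * delta
    }
  }
  acc <- numeric(0)
  drawn <- 0L
  # chunk policy matches the exact-path sampler so that, under a common seed,
  # both modes consume the same candidate/uniform stream
  chunk <- max(64L, 4L * n_samples)
  while (length(acc) < n_samples) {
    if (drawn >= max_draws) abort("accept-reject exceeded the candidate draw cap.")
    cand <- runif(chunk)
    u <- runif(chunk)
    pos <- (cand - cache$h[1]) / cache$step
    lo <- pmin(pmax(floor(pos), 0), ng - 2L)
    frac <- pos - lo # < 0 / > 1 beyond the grid: linear extrapolation
    lpc <- lp[lo + 1L] * (1 - frac) + lp[lo + 2L] * frac
    bad <- !is.finite(lpc) # -Inf neighbours: snap to the nearest grid value
    if (any(bad)) {
      lpc[bad] <- lp[pmin(pmax(round(pos[bad]), 0), ng - 1L) + 1L]
    }
    ratio <- pmin(exp(lpc - lpmax), 1)
    acc <- c(acc, cand[u <= ratio])
    drawn <- drawn + chunk
  }
  acc[seq_len(n_samples)]
}

# Vectorized HKp over the columns of X. Per-column RNG substreams derived
# from `seed` keep each series' estimate independent of batch composition.
hkp_estimate_matrix <- function(X, cache, seed, n_samples = 50L) {
  lp <- hk_logpost_grid(X, cache)
  m <- ncol(X)
  out <- numeric(m)
  for (j in seq_len(m)) {
    out[j] <- with_seed_(
      derive_seed(seed, 811L, j),
      median(ar_sample_grid(lp[, j], cache, n_samples))
    )
  }
  out
}
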