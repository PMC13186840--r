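#' Autocorrelation function of the Hurst-Kolmogorov process
#'
#' Evaluates the theoretical autocorrelation of fractional Gaussian noise
#' (the stationary increments of the Hurst-Kolmogorov process) at lags
#' `0..max_lag`:
#' \deqn{\rho_k = \tfrac12 |k+1|^{2H} + \tfrac12 |k-1|^{2H} - |k|^{2H}.}
#' At `H = 0.5` all lags beyond 0 vanish (white noise); for `H > 0.5` the
#' correlations are positive and decay slowly (persistence); for `H < 0.5`
#' the lag-1 correlation is negative (anti-persistence).
#'
#' @param hurst Hurst exponent, in (0, 1].
#' @param max_lag Largest lag K to evaluate (non-negative integer).
#' @return Numeric vector of length `max_lag + 1` with `rho[k + 1]` the
#'   autocorrelation at lag `k`.
#' @examples
#' hk_acf(0.75, 5)
#' hk_acf(0.5, 3) # c(1, 0, 0, 0)
#' @export
hk_acf <- function(hurst, max_lag) {
  assert_scalar_prob(hurst, "hurst", lo = 0, hi = 1, hi_open = FALSE)
  if (!is.numeric(max_lag) || length(max_lag) != 1L || max_lag < 0 ||
      max_lag != floor(max_lag)) {
    abort("`max_lag` must be a single non-negative integer.")
  }
  k <- 0:max_lag
  0.5 * abs(k + 1)^(2 * hurst) + 0.5 * abs(k - 1)^(2 * hurst) - abs(k)^(2 * hurst)
}

# Davies-Harte / circulant embedding sampler. Returns an n x m matrix whose
# columns are independent fGn(hurst) series with the exact target ACF.
# Falls back to Cholesky of the dense Toeplitz covariance if the circulant
# eigenvalues are not all (numerically) nonnegative.
fgn_matrix <- function(hurst, n, m = 1L, sd = 1) {
  assert_scalar_prob(hurst, "hurst")
  if (n < 8) abort("`n` must be at least 8.")
  if (sd <= 0) abort("`sd` must be positive.")
  gamma <- sd^2 * hk_acf(hurst, n) # lags 0..n
  # first row of the 2n-circulant embedding
  circ <- c(gamma[1:(n + 1)], gamma[n:2])
  lambda <- Re(fft(circ))
  if (min(lambda) < -1e-8 * max(lambda)) {
    return(fgn_matrix_chol(gamma[1:n], n, m))
  }
  lambda <- pmax(lambda, 0)
  M <- 2L * n
  # Hermitian-symmetric complex Gaussian spectrum; 2n normals per series,
  # drawn in a fixed order so results are reproducible under set.seed().
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    z1 <- rnorm(n + 1L) # components 0..n
    z2 <- rnorm(n - 1L) # imaginary parts for 1..n-1
    v <- complex(length.out = M)
    v[1] <- sqrt(lambda[1]) * z1[1]
    v[n + 1] <- sqrt(lambda[n + 1]) * z1[n + 1]
    idx <- 2:n
    v[idx] <- sqrt(lambda[idx] / 2) * complex(real = z1[idx], imaginary = z2)
    v[M:(n + 2)] <- Conj(v[idx])
    x <- Re(fft(v)) / sqrt(M)
    out[, j] <- x[1:n]
  }
  out
}

fgn_matrix_chol <- function(gamma_0_nm1, n, m) {
  R <- stats::toeplitz(gamma_0_nm1)
  L <- tryCatch(chol(R), error = function(e) {
    chol(R + diag(1e-10 * gamma_0_nm1[1], n))
  })
  z <- matrix(rnorm(n * m), n, m)
  crossprod(L, z)
}

#' Simulate fractional Gaussian noise
#'
#' Draws one stationary Gaussian series with mean 0, standard deviation `sd`
#' and the exact Hurst-Kolmogorov autocorrelation [hk_acf()] at every lag.
#' Uses circulant embedding (Davies-Harte), which is exact, with a dense
#' covariance-Cholesky fallback for the rare embeddings that are not
#' nonnegative definite.
#'
#' @param hurst Hurst exponent in (0, 1).
#' @param n Series length (>= 8).
#' @param sd Marginal standard deviation of the series (> 0).
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched and the draw is reproducible.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- simulate_fgn(0.75, 128, seed = 1)
#' @export
simulate_fgn <- function(hurst, n, sd = 1, seed = NULL) {
  with_seed_(seed, drop(fgn_matrix(hurst, n, 1L, sd)))
}

#' Draw correlated trial-level true Hurst exponents
#'
#' Samples, for each subject, `n_trials` true Hurst values from a multivariate
#' normal with common marginal mean and standard deviation and a
#' compound-symmetry (equicorrelation) structure, realized through the
#' Cholesky factor of that covariance. This reproduces a chosen between-trial
#' intraclass correlation among a subject's trials.
#'
#' Draws outside (0, 1) would leave the support of the fGn generator. Two
#' handling schemes are available. `"clamp"` (default) winsorizes offending
#' values to the edge of the representable range; at the reference design's
#' means this perturbs the realized group mean by well under 1% of the SD,
#' so the nominal between-group difference is preserved. `"resample"`
#' rejects and redraws any subject row containing an out-of-range value;
#' this keeps the distribution Gaussian-shaped but, when the mean sits
#' within ~1.5 SD of a bound, visibly shrinks the realized mean difference.
#' Either way the number of affected rows is reported.
#'
#' @param n_subjects Number of subjects (rows).
#' @param n_trials Trials per subject (columns).
#' @param mean Marginal mean of true H, in (0, 1).
#' @param sd Marginal standard deviation of true H (> 0).
#' @param icc Common correlation between any two trials of a subject, in \[0, 1\].
#' @param support Out-of-range handling: `"clamp"` or `"resample"`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `subject`, `trial`, `true_h`, carrying the
#'   attribute `n_resampled` (rows touched by support handling).
#' @examples
#' h <- sample_trial_h(100, 4, mean = 0.75, sd = 0.11, icc = 0.65, seed = 7)
#' @export
sample_trial_h <- function(n_subjects, n_trials, mean = 0.75, sd = 0.11,
                           icc = 0.65, support = c("clamp", "resample"),
                           seed = NULL) {
  support <- match.arg(support)
  H <- with_seed_(seed, trial_h_matrix(n_subjects, n_trials, mean, sd, icc, support))
  out <- tibble::tibble(
    subject = rep(seq_len(n_subjects), each = n_trials),
    trial = rep(seq_len(n_trials), times = n_subjects),
    true_h = as.vector(t(H))
  )
  attr(out, "n_resampled") <- attr(H, "n_resampled")
  out
}

# Matrix workhorse: n_subjects x n_trials matrix of true H values.
# H values must stay inside the fGn support; the representable band matches
# the HKp evaluation range.
H_SUPPORT_EPS <- 0.005

trial_h_matrix <- function(n_subjects, n_trials, mean, sd, icc,
                           support = "clamp") {
  assert_scalar_prob(mean, "mean")
  assert_scalar_prob(icc, "icc", lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE)
  if (sd <= 0) abort("`sd` must be positive.")
  Sigma <- sd^2 * ((1 - icc) * diag(n_trials) + icc * matrix(1, n_trials, n_trials))
  L <- if (icc < 1) chol(Sigma) else NULL
  draw <- function(k) {
    if (icc < 1) {
      mean + matrix(rnorm(k * n_trials), k, n_trials) %*% L
    } else {
      mean + sd * matrix(rnorm(k), k, n_trials)
    }
  }
  H <- draw(n_subjects)
  out_of_range <- function(M) M <= H_SUPPORT_EPS | M >= 1 - H_SUPPORT_EPS
  if (support == "clamp") {
    bad <- out_of_range(H)
    n_resampled <- sum(apply(bad, 1L, any))
    H <- pmin(pmax(H, H_SUPPORT_EPS), 1 - H_SUPPORT_EPS)
  } else {
    bad <- which(apply(out_of_range(H), 1L, any))
    n_resampled <- 0L
    while (length(bad)) {
      n_resampled <- n_resampled + length(bad)
      H[bad, ] <- draw(length(bad))
      bad <- bad[apply(out_of_range(H[bad, , drop = FALSE]), 1L, any)]
      if (n_resampled > 1e6) abort("trial-H rejection sampling failed to terminate.")
    }
  }
  attr(H, "n_resampled") <- n_resampled
  H
}
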