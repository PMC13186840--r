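#' Integrate a series for detrended fluctuation analysis
#'
#' Forms the DFA profile: the cumulative sum of the mean-centered series.
#' Centering before integration makes the downstream scaling exponent
#' invariant to shifts and positive rescalings of the raw data; the last
#' profile value is zero up to rounding.
#'
#' @param x Numeric series (length >= 8).
#' @return Numeric profile of the same length as `x`.
#' @export
integrate_series <- function(x) {
  assert_series(x)
  cumsum(x - mean(x))
}

#' Fluctuation function at one window size
#'
#' Splits the profile into `floor(N / n)` non-overlapping windows of size `n`
#' anchored at the start (trailing remainder discarded), removes a linear
#' ordinary-least-squares trend inside each window, and returns
#' `F(n) = sqrt(mean squared residual)` over all retained points.
#'
#' @param profile Integrated series, as returned by [integrate_series()].
#' @param n Window size, an integer in `[4, floor(N/2)]` (at least two full
#'   windows; the DFA fit itself only uses scales up to `floor(N/4)`).
#' @return The scalar fluctuation `F(n) >= 0`.
#' @export
fluctuation_at_scale <- function(profile, n) {
  N <- length(profile)
  if (!is.numeric(n) || length(n) != 1L || n != floor(n)) {
    abort("`n` must be a single integer.")
  }
  if (n < 4 || n > N %/% 2) {
    abort(sprintf("scale %d outside the admissible range [4, %d].", n, N %/% 2))
  }
  drop(fluctuations_matrix(matrix(profile, ncol = 1L), as.integer(n)))
}

# F(n) for each column of a profile matrix, at a single scale.
# Linear detrending is a fixed projection per scale, so all windows of all
# series are detrended with one QR residual call.
fluctuations_matrix <- function(P, n) {
  N <- nrow(P)
  m <- ncol(P)
  nw <- N %/% n
  W <- P[seq_len(nw * n), , drop = FALSE]
  dim(W) <- c(n, nw * m)
  qrD <- qr(cbind(1, seq_len(n)))
  res <- qr.resid(qrD, W)
  msq <- colMeans(matrix(colMeans(res^2), nw, m))
  sqrt(msq)
}

# Full DFA on each column of X: returns list(alpha, intercept, r_squared,
# scales, F) with F a length(scales) x m matrix. Scales are every integer in
# [min_scale, floor(N/4)] (or a supplied max).
dfa_matrix <- function(X, min_scale = 4L, max_scale = NULL) {
  N <- nrow(X)
  max_scale <- max_scale %||% (N %/% 4L)
  if (max_scale < min_scale) abort("series too short for the requested scale range.")
  scales <- seq.int(min_scale, max_scale)
  P <- apply(X, 2L, function(col) cumsum(col - mean(col)))
  P <- matrix(P, nrow = N)
  Fm <- vapply(scales, function(s) fluctuations_matrix(P, s), numeric(ncol(X)))
  Fm <- matrix(t(Fm), nrow = length(scales)) # scales x m
  lx <- log(scales)
  fit_one <- function(fv) {
    ok <- fv > 0
    if (sum(ok) < 3L) {
      return(c(alpha = NA_real_, intercept = NA_real_, r_squared = NA_real_))
    }
    ly <- log(fv[ok])
    cf <- stats::lm.fit(cbind(1, lx[ok]), ly)$coefficients
    ssr <- sum((ly - cf[1] - cf[2] * lx[ok])^2)
    sst <- sum((ly - mean(ly))^2)
    c(alpha = unname(cf[2]), intercept = unname(cf[1]),
      r_squared = if (sst > 0) 1 - ssr / sst else NA_real_)
  }
  stats_m <- apply(Fm, 2L, fit_one)
  list(
    alpha = stats_m["alpha", ], intercept = stats_m["intercept", ],
    r_squared = stats_m["r_squared", ], scales = scales, F = Fm
  )
}

#' Detrended fluctuation analysis
#'
#' Estimates the scaling exponent alpha (the Hurst exponent H for stationary
#' series) by DFA: integrate the mean-centered series, compute the fluctuation
#' function F(n) with linear detrending at every integer window size from
#' `min_scale` to `floor(N/4)`, and fit an unweighted ordinary least squares
#' line to log F(n) versus log n. The dense integer scale grid suits short
#' stride series, where coarser log-spaced grids leave too few fit points.
#' Scales with `F(n) == 0` (possible only for degenerate inputs) are excluded
#' from the fit and flagged in the per-scale table.
#'
#' @param x Numeric series of length >= 16.
#' @param min_scale Smallest window size (default 4).
#' @param max_scale Largest window size; default `floor(length(x) / 4)`.
#' @return An object of class `c("dfa_estimate", "hurst_estimate")`: a list
#'   with `method = "DFA"`, the point estimate `point` (alpha), `intercept`,
#'   `r_squared`, and a per-scale tibble `fit` with columns `scale`,
#'   `fluctuation`, `used`. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @examples
#' x <- simulate_fgn(0.9, 500, seed = 42)
#' fit <- dfa_estimate(x)
#' fit$point
#' @export
dfa_estimate <- function(x, min_scale = 4L, max_scale = NULL) {
  assert_series(x, min_length = 16L)
  res <- dfa_matrix(matrix(x, ncol = 1L), min_scale = min_scale, max_scale = max_scale)
  fv <- drop(res$F)
  if (sum(fv > 0) < 3L) abort("fewer than 3 scales with positive fluctuation; DFA fit undefined.")
  structure(
    list(
      method = "DFA",
      point = unname(res$alpha),
      intercept = unname(res$intercept),
      r_squared = unname(res$r_squared),
      n = length(x),
      fit = tibble::tibble(scale = res$scales, fluctuation = fv, used = fv > 0)
    ),
    class = c("dfa_estimate", "hurst_estimate")
  )
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat(sprintf("<%s Hurst estimate>\n", x$method))
  cat(sprintf("  point estimate: %.4f  (series length %d)\n", x$point, x$n))
  if (x$method == "DFA") {
    cat(sprintf("  scales: %d..%d (%d), R^2 = %.4f\n",
                min(x$fit$scale), max(x$fit$scale), nrow(x$fit), x$r_squared))
  } else {
    cat(sprintf("  posterior peak at H = %.4f; %d accept-reject samples\n",
                x$peak_h, length(x$samples)))
  }
  invisible(x)
}
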