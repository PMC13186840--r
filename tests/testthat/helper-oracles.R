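# Independent oracles, deliberately written as naive loops / dense algebra
# so they share no code path with the package implementation.

# Brute-force DFA: explicit window loops, per-window polyfit, unweighted
# log-log regression over all integer scales 4..floor(N/4).
oracle_dfa <- function(x) {
  N <- length(x)
  prof <- cumsum(x - mean(x))
  scales <- 4:(N %/% 4)
  Fv <- numeric(length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    nw <- N %/% s
    sq <- c()
    for (w in seq_len(nw)) {
      idx <- ((w - 1) * s + 1):(w * s)
      seg <- prof[idx]
      t <- seq_len(s)
      fit <- lm(seg ~ t)
      sq <- c(sq, residuals(fit)^2)
    }
    Fv[si] <- sqrt(mean(sq))
  }
  ok <- Fv > 0
  co <- coef(lm(log(Fv[ok]) ~ log(scales[ok])))
  list(alpha = unname(co[2]), scales = scales, F = Fv)
}

# F(n) for one scale by the same explicit loops.
oracle_fluctuation <- function(prof, s) {
  N <- length(prof)
  nw <- N %/% s
  sq <- c()
  for (w in seq_len(nw)) {
    idx <- ((w - 1) * s + 1):(w * s)
    t <- seq_len(s)
    sq <- c(sq, residuals(lm(prof[idx] ~ t))^2)
  }
  sqrt(mean(sq))
}

# Dense-inverse HK log posterior (explicit solve() and determinant()).
oracle_log_posterior <- function(x, h) {
  n <- length(x)
  k <- 0:(n - 1)
  rho <- 0.5 * abs(k + 1)^(2 * h) + 0.5 * abs(k - 1)^(2 * h) - abs(k)^(2 * h)
  R <- stats::toeplitz(rho)
  Ri <- solve(R)
  one <- rep(1, n)
  s1 <- drop(t(one) %*% Ri %*% one)
  sx <- drop(t(one) %*% Ri %*% x)
  q <- drop(t(x) %*% Ri %*% x) - sx^2 / s1
  ld <- as.numeric(determinant(R, logarithm = TRUE)$modulus)
  -0.5 * ld - 0.5 * log(s1) - ((n - 1) / 2) * log(q)
}

# ICC(3,k) through base R's aov() decomposition.
oracle_icc_3k <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  d <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(n), k)),
    meas = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(y ~ subj + meas, data = d))[[1]]
  bms <- tab["subj", "Mean Sq"]
  ems <- tab["Residuals", "Mean Sq"]
  (bms - ems) / bms
}

# Grid-integrated posterior CDF evaluated at arbitrary points. Each grid
# point's probability mass is treated as centered on the point (midpoint
# rule), so the CDF at a grid point includes half of that point's mass —
# without this the rectangle rule misplaces up to half a bin of mass at
# the density peak.
oracle_posterior_cdf <- function(x, at, grid = seq(0.0025, 0.9975, by = 0.005)) {
  lp <- vapply(grid, function(h) hk_log_posterior(x, h), 0)
  d <- exp(lp - max(lp))
  cdf <- (cumsum(d) - d / 2) / sum(d)
  stats::approx(grid, cdf, xout = at, yleft = 0, yright = 1, rule = 2)$y
}
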