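#' Define one power-simulation condition
#'
#' Bundles and validates the parameters of a two-group comparison of mean
#' Hurst exponent: group A has mean true H `mean_a`, group B
#' `mean_a + delta_h`; each subject contributes `n_trials` trials whose true
#' H values share a compound-symmetry correlation `trial_icc` with marginal
#' SD `within_sd`; each trial is an fGn series of `series_length` strides;
#' H is estimated per trial by `method`, averaged within subject, and the
#' group means compared by a two-sided two-sample t-test at level `alpha`.
#'
#' @param delta_h Between-group difference in mean true H (>= 0).
#' @param n_per_group Subjects per group.
#' @param n_trials Trials per subject (1-4 in the reference design).
#' @param series_length Strides per trial.
#' @param method `"hkp"`, `"dfa"`, or `"true"` (no estimation: the true
#'   subject-mean H feeds the test; useful for analytic calibration).
#' @param reps Monte-Carlo replicates.
#' @param mean_a Group A mean true H (default 0.75).
#' @param within_sd Within-group SD of true H (default 0.11).
#' @param trial_icc Between-trial correlation of true H (default 0.65).
#' @param alpha Test level (default 0.05).
#' @param welch Use the Welch (unequal-variance) t-test (default `TRUE`);
#'   `FALSE` pools variances. With equal group sizes and equal design SDs
#'   the two are practically indistinguishable.
#' @param support Handling of true-H draws outside (0, 1): `"clamp"`
#'   (winsorize; preserves the nominal group means, the default) or
#'   `"resample"` (subject-row rejection; see [sample_trial_h()]).
#' @param seed Master seed; every replicate derives its own substream.
#' @return A validated list of class `power_condition`.
#' @export
power_condition <- function(delta_h, n_per_group, n_trials = 1L,
                            series_length = 100L, method = c("hkp", "dfa", "true"),
                            reps = 1000L, mean_a = 0.75, within_sd = 0.11,
                            trial_icc = 0.65, alpha = 0.05, welch = TRUE,
                            support = c("clamp", "resample"), seed = 1L) {
  method <- match.arg(tolower(method[1]), c("hkp", "dfa", "true"))
  support <- match.arg(support)
  if (delta_h < 0) abort("`delta_h` must be nonnegative.")
  assert_scalar_prob(mean_a + delta_h, "mean_a + delta_h")
  assert_scalar_prob(alpha, "alpha")
  if (n_per_group < 2) abort("`n_per_group` must be at least 2.")
  if (reps < 1) abort("`reps` must be at least 1.")
  if (method != "true" && series_length < 16) {
    abort("`series_length` must be at least 16 for estimation.")
  }
  structure(
    list(delta_h = delta_h, n_per_group = as.integer(n_per_group),
         n_trials = as.integer(n_trials), series_length = as.integer(series_length),
         method = method, reps = as.integer(reps), mean_a = mean_a,
         within_sd = within_sd, trial_icc = trial_icc, alpha = alpha,
         welch = welch, support = support, seed = as.integer(seed)),
    class = "power_condition"
  )
}

#' @export
print.power_condition <- function(x, ...) {
  cat(sprintf(
    "<power_condition: dH=%.3f, n=%d/group, %d trial(s) x %d strides, %s, %d reps, alpha=%.2f>\n",
    x$delta_h, x$n_per_group, x$n_trials, x$series_length, toupper(x$method),
    x$reps, x$alpha
  ))
  invisible(x)
}

# Subject-mean H estimates for one replicate at the maximal group size.
# Returns list(a, b): numeric vectors of length n_max. All randomness comes
# from substreams of rep_seed, in a fixed order, so results for the first n
# subjects do not depend on n_max beyond sharing the stream (common random
# numbers are obtained by subsetting).
replicate_subject_means <- function(cond, n_max, rep_seed, cache = NULL) {
  hA <- with_seed_(derive_seed(rep_seed, 1L),
                   trial_h_matrix(n_max, cond$n_trials, cond$mean_a,
                                  cond$within_sd, cond$trial_icc, cond$support))
  hB <- with_seed_(derive_seed(rep_seed, 2L),
                   trial_h_matrix(n_max, cond$n_trials, cond$mean_a + cond$delta_h,
                                  cond$within_sd, cond$trial_icc, cond$support))
  if (cond$method == "true") {
    return(list(a = rowMeans(hA), b = rowMeans(hB)))
  }
  len <- cond$series_length
  hall <- c(t(hA), t(hB)) # subject-major, trials within subject; A then B
  X <- matrix(0, len, length(hall))
  for (j in seq_along(hall)) {
    X[, j] <- with_seed_(derive_seed(rep_seed, 3L, j),
                         drop(fgn_matrix(hall[j], len, 1L, 1)))
  }
  est <- if (cond$method == "dfa") {
    dfa_matrix(X)$alpha
  } else {
    hkp_estimate_matrix(X, cache, seed = derive_seed(rep_seed, 4L))
  }
  em <- matrix(est, nrow = cond$n_trials) # trials x (2 * n_max)
  means <- colMeans(em)
  list(a = means[seq_len(n_max)], b = means[n_max + seq_len(n_max)])
}

# Vectorized two-sided two-sample t-test p-values from group summary rows.
# ma, mb: reps x 1 means; va, vb variances; na, nb sizes.
t_test_pvals <- function(ma, va, na, mb, vb, nb, welch = TRUE) {
  if (welch) {
    se2a <- va / na
    se2b <- vb / nb
    tt <- (ma - mb) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  2 * pt(-abs(tt), df)
}

#' Run one replicate of a power condition
#'
#' Draws both groups' correlated trial-level true H values, simulates one
#' fGn series per trial, estimates H per trial by the condition's method,
#' averages within subject, and applies the two-sample t-test.
#'
#' @param condition A [power_condition()].
#' @param replicate_seed Integer seed for this replicate.
#' @param cache Optional [hk_grid_cache()] for the condition's series length
#'   (built on the fly when needed).
#' @return Logical: was the null hypothesis rejected at the condition's
#'   `alpha`? The p-value is attached as attribute `p_value`.
#' @export
simulate_replicate <- function(condition, replicate_seed, cache = NULL) {
  stopifnot(inherits(condition, "power_condition"))
  if (condition$method == "hkp" && is.null(cache)) {
    cache <- hk_grid_cache(condition$series_length)
  }
  sm <- replicate_subject_means(condition, condition$n_per_group,
                                replicate_seed, cache)
  p <- t_test_pvals(mean(sm$a), var(sm$a), length(sm$a),
                    mean(sm$b), var(sm$b), length(sm$b), condition$welch)
  structure(p < condition$alpha, p_value = p)
}

# Engine shared by estimate_power() / min_n_for_power() / power curves:
# runs `reps` replicates at n_max subjects per group and returns the
# rejection indicator for every n in n_grid (common random numbers: smaller
# n reuse the leading subjects of the same replicate).
power_scan <- function(cond, n_grid) {
  n_grid <- sort(unique(as.integer(n_grid)))
  n_max <- max(n_grid)
  cache <- if (cond$method == "hkp") hk_grid_cache(cond$series_length) else NULL
  A <- matrix(NA_real_, cond$reps, n_max)
  B <- matrix(NA_real_, cond$reps, n_max)
  for (r in seq_len(cond$reps)) {
    sm <- replicate_subject_means(cond, n_max, derive_seed(cond$seed, 7L, r), cache)
    A[r, ] <- sm$a
    B[r, ] <- sm$b
  }
  rej <- matrix(NA, cond$reps, length(n_grid))
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    ma <- rowMeans(A[, seq_len(n), drop = FALSE])
    mb <- rowMeans(B[, seq_len(n), drop = FALSE])
    va <- apply(A[, seq_len(n), drop = FALSE], 1L, var)
    vb <- apply(B[, seq_len(n), drop = FALSE], 1L, var)
    rej[, i] <- t_test_pvals(ma, va, n, mb, vb, n, cond$welch) < cond$alpha
  }
  list(n_grid = n_grid, rejections = colSums(rej), reps = cond$reps)
}

power_result_row <- function(cond, n, rejections, reps) {
  ci <- stats::binom.test(rejections, reps)$conf.int
  tibble::tibble(
    delta_h = cond$delta_h, n_per_group = as.integer(n),
    n_trials = cond$n_trials, series_length = cond$series_length,
    method = toupper(cond$method), reps = as.integer(reps),
    rejections = as.integer(rejections), power = rejections / reps,
    ci_low = ci[1], ci_high = ci[2], seed = cond$seed
  )
}

#' Estimate statistical power for one condition
#'
#' Monte-Carlo power: the proportion of replicates in which the two-group
#' t-test rejects at the condition's level, with an exact (Clopper-Pearson)
#' 95% binomial confidence interval.
#'
#' @param condition A [power_condition()].
#' @return One-row tibble: the condition parameters, `rejections`, `power`
#'   (`= rejections / reps`), `ci_low`, `ci_high`.
#' @examples
#' cond <- power_condition(0.12, n_per_group = 15, method = "true",
#'                         reps = 200, seed = 5)
#' estimate_power(cond)
#' @export
estimate_power <- function(condition) {
  stopifnot(inherits(condition, "power_condition"))
  scan <- power_scan(condition, condition$n_per_group)
  power_result_row(condition, condition$n_per_group, scan$rejections[1], scan$reps)
}

#' Power curve over a grid of group sizes
#'
#' Evaluates the power of a condition template at every group size in
#' `n_grid`, reusing the same simulated subjects across sizes (common random
#' numbers): each replicate is simulated once at `max(n_grid)` subjects per
#' group and smaller sizes test its leading subjects, which removes most
#' Monte-Carlo jitter between adjacent grid points.
#'
#' @param condition A [power_condition()]; its `n_per_group` is ignored.
#' @param n_grid Integer vector of group sizes.
#' @return Tibble with one row per grid size (see [estimate_power()]).
#' @export
power_curve <- function(condition, n_grid) {
  stopifnot(inherits(condition, "power_condition"))
  scan <- power_scan(condition, n_grid)
  out <- purrr::map_dfr(seq_along(scan$n_grid), function(i) {
    power_result_row(condition, scan$n_grid[i], scan$rejections[i], scan$reps)
  })
  class(out) <- c("power_curve", class(out))
  out
}

#' Minimum group size reaching a target power
#'
#' Scans an ascending grid of group sizes with common random numbers and
#' returns the smallest size whose estimated power reaches `target`. When no
#' grid size attains the target the result is `NA` with `attained = FALSE`
#' (read: "> max(n_grid)").
#'
#' @param condition A [power_condition()] template (`n_per_group` ignored).
#' @param n_grid Ascending integer grid of candidate group sizes.
#' @param target Target power (default 0.8).
#' @return List of class `min_n_result`: `min_n` (integer or `NA`),
#'   `attained`, `target`, and the full `curve` tibble.
#' @export
min_n_for_power <- function(condition, n_grid, target = 0.8) {
  curve <- power_curve(condition, n_grid)
  hit <- which(curve$power >= target)
  structure(
    list(
      min_n = if (length(hit)) curve$n_per_group[min(hit)] else NA_integer_,
      attained = length(hit) > 0,
      target = target,
      max_n_searched = max(curve$n_per_group),
      curve = curve
    ),
    class = "min_n_result"
  )
}

#' @export
print.min_n_result <- function(x, ...) {
  if (x$attained) {
    cat(sprintf("minimum n per group for power >= %.2f: %d\n", x$target, x$min_n))
  } else {
    cat(sprintf("power >= %.2f not attained: min n > %d\n",
                x$target, x$max_n_searched))
  }
  invisible(x)
}

#' Batch power table over a design grid
#'
#' Runs [estimate_power()] for every row of a condition grid (as produced by
#' e.g. [tidyr::expand_grid()]) and binds the tidy results. Each row derives
#' its own seed from `seed`, so the table is reproducible and any single row
#' can be re-run in isolation.
#'
#' @param conditions Data frame whose columns are [power_condition()]
#'   arguments (`delta_h`, `n_per_group`, `n_trials`, `series_length`,
#'   `method`, ...).
#' @param reps Replicates per condition.
#' @param seed Master seed.
#' @return Tibble with one row per condition.
#' @export
power_table <- function(conditions, reps = 1000L, seed = 1L) {
  stopifnot(is.data.frame(conditions), nrow(conditions) > 0)
  purrr::map_dfr(seq_len(nrow(conditions)), function(i) {
    row <- as.list(conditions[i, , drop = FALSE])
    row$reps <- row$reps %||% reps
    row$seed <- derive_seed(seed, 41L, i)
    cond <- do.call(power_condition, row)
    estimate_power(cond)
  })
}
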