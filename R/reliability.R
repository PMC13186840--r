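#' Keep the last n strides of a series
#'
#' Selects the final `n` consecutive values, preserving order (and grouping
#' labels when `x` is a long-format table). Slicing from the end of a trial
#' rather than the beginning avoids familiarization effects at walking onset.
#'
#' @param x Numeric vector, or a long-format stride table with a `value`
#'   column and trial identifier columns.
#' @param n Number of strides to retain; every series must be at least this
#'   long.
#' @return Object of the same shape as `x`, shortened to `n` strides per
#'   series.
#' @export
slice_last_strides <- function(x, n) {
  if (is.data.frame(x)) {
    by <- intersect(c("subject", "group", "day", "trial", "variable"), names(x))
    out <- dplyr::slice_tail(dplyr::group_by(x, dplyr::across(dplyr::all_of(by))),
                             n = n)
    counts <- dplyr::count(out)
    if (any(counts$n < n)) {
      abort(sprintf("some series are shorter than n = %d strides.", n))
    }
    return(dplyr::ungroup(out))
  }
  if (length(x) < n) {
    abort(sprintf("series of length %d is shorter than n = %d.", length(x), n))
  }
  x[seq.int(length(x) - n + 1L, length(x))]
}

#' Average the first k trials of each subject-day
#'
#' Collapses per-trial Hurst estimates to one value per subject and day: the
#' arithmetic mean of trials `1..k`, taken in trial-number (acquisition)
#' order on both days.
#'
#' @param estimates Tibble with columns `subject`, `day`, `trial`, and an
#'   estimate column `h` (as produced by [estimate_hurst()]); extra
#'   identifier columns (`group`, `variable`, `method`) are carried through.
#' @param k Number of trials to average (each subject-day must have trials
#'   `1..k`).
#' @return Tibble with one row per subject-day and column `h_mean`.
#' @export
day_average <- function(estimates, k) {
  needed <- c("subject", "day", "trial", "h")
  if (!all(needed %in% names(estimates))) {
    abort("`estimates` must have columns subject, day, trial, h.")
  }
  keep <- estimates[estimates$trial %in% seq_len(k), , drop = FALSE]
  by <- intersect(c("subject", "group", "day", "variable", "method"), names(keep))
  out <- dplyr::summarise(
    dplyr::group_by(keep, dplyr::across(dplyr::all_of(by))),
    n_trials = dplyr::n(),
    h_mean = mean(.data$h),
    .groups = "drop"
  )
  if (any(out$n_trials < k)) abort(sprintf("fewer than k = %d trials available.", k))
  dplyr::select(out, -"n_trials")
}

#' Qualitative reliability band of an ICC value
#'
#' Bands: poor (< 0.5), moderate (0.5 to < 0.75), good (0.75 to < 0.9),
#' excellent (>= 0.9). Values exactly on a boundary take the upper band.
#'
#' @param icc Numeric vector of ICC values.
#' @return Factor with levels poor, moderate, good, excellent.
#' @export
icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent"))
}

#' Intraclass correlation ICC(3,k): two-way mixed effects, consistency
#'
#' Average-measures consistency ICC from a two-way (subjects x measurements)
#' ANOVA decomposition: `ICC(3,k) = (BMS - EMS) / BMS`, with BMS the
#' between-subjects mean square and EMS the residual mean square after
#' removing the fixed measurement (e.g. day) effect. A constant offset
#' between measurements therefore leaves the ICC at 1. The 95% confidence
#' interval follows the Shrout-Fleiss F-bounds on `BMS/EMS`.
#'
#' @param x Numeric matrix with one row per subject and one column per
#'   repeated measurement (k >= 2, no missing cells), or a data frame with
#'   columns `subject`, a measurement column (default `day`), and a value
#'   column (default `h_mean`).
#' @param measure,value Column names used when `x` is a data frame.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row tibble: `icc`, `f_stat`, `df1`, `df2`, `ci_low`,
#'   `ci_high`, `band`.
#' @examples
#' m <- cbind(c(0.70, 0.80, 0.60, 0.90), c(0.72, 0.79, 0.64, 0.88))
#' icc_3k(m)
#' @export
icc_3k <- function(x, measure = "day", value = "h_mean", conf_level = 0.95) {
  if (is.data.frame(x)) {
    if (!all(c("subject", measure, value) %in% names(x))) {
      abort(sprintf("`x` must have columns subject, %s, %s.", measure, value))
    }
    wide <- tidyr::pivot_wider(
      x[, c("subject", measure, value)],
      names_from = dplyr::all_of(measure), values_from = dplyr::all_of(value)
    )
    x <- as.matrix(wide[, -1, drop = FALSE])
  }
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3L) abort("ICC(3,k) needs at least 3 subjects.")
  if (k < 2L) abort("ICC(3,k) needs at least 2 repeated measurements.")
  if (anyNA(x)) abort("ICC(3,k) requires complete data (no missing cells).")

  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  bms <- ss_rows / df1
  ems <- ss_err / df2
  if (bms <= 0) abort("zero between-subject variance: ICC(3,k) undefined.")
  icc <- (bms - ems) / bms
  f_stat <- bms / ems
  alpha <- 1 - conf_level
  fl <- f_stat / qf(1 - alpha / 2, df1, df2)
  fu <- f_stat * qf(1 - alpha / 2, df2, df1)
  tibble::tibble(
    icc = icc, f_stat = f_stat, df1 = df1, df2 = df2,
    ci_low = 1 - 1 / fl, ci_high = 1 - 1 / fu,
    band = icc_band(icc)
  )
}

#' Between-day reliability grid over stride counts and trials averaged
#'
#' Replays the reliability design on a cohort: for each stride count `s` and
#' each number of trials `k`, slice the last `s` strides of every trial,
#' estimate H per trial, average trials `1..k` within each subject-day, and
#' compute the between-day ICC(3,k) over subjects. The grid is computed
#' separately per group and variable. Per-trial estimates are computed once
#' per stride count and reused across all `k`, so the grid costs no more
#' than its largest row.
#'
#' @param cohort A `hurst_cohort` (from [generate_cohort()]) or a long-format
#'   stride table; with `method = "true"` a truth table with `true_h`.
#' @param method `"dfa"`, `"hkp"`, or `"true"` (bypass estimation and use
#'   recorded true H values — useful for validating the design itself).
#' @param stride_counts Integer vector of stride counts (x axis).
#' @param trials Integer vector of trials-averaged values (y axis).
#' @param seed Optional integer seed (HKp sampling).
#' @return Tibble of class `reliability_grid`: columns `group`, `variable`,
#'   `method`, `stride_count`, `trials_used`, `icc`, `ci_low`, `ci_high`,
#'   `band`. Cells whose ICC is undefined carry `NA` and are kept, never
#'   dropped. Supports [ggplot2::autoplot()].
#' @export
reliability_grid <- function(cohort, method = c("hkp", "dfa", "true"),
                             stride_counts = 50:173, trials = 1:9,
                             seed = NULL) {
  method <- match.arg(tolower(method[1]), c("hkp", "dfa", "true"))
  if (inherits(cohort, "hurst_cohort")) {
    series <- cohort$series
    truth <- cohort$truth
  } else {
    series <- cohort
    truth <- cohort
  }

  grid_for_est <- function(est) {
    # est: per-trial H table -> ICC for each k
    purrr::map_dfr(trials, function(k) {
      avg <- day_average(est, k)
      cells <- dplyr::group_split(dplyr::group_by(
        avg, dplyr::across(dplyr::any_of(c("group", "variable")))))
      purrr::map_dfr(cells, function(cell) {
        lab <- cell[1, intersect(c("group", "variable"), names(cell)), drop = FALSE]
        res <- tryCatch(icc_3k(cell), error = function(e) {
          tibble::tibble(icc = NA_real_, f_stat = NA_real_, df1 = NA_integer_,
                         df2 = NA_integer_, ci_low = NA_real_, ci_high = NA_real_,
                         band = icc_band(NA_real_))
        })
        dplyr::bind_cols(tibble::as_tibble(lab), tibble::tibble(trials_used = k), res)
      })
    })
  }

  out <- purrr::map_dfr(stride_counts, function(s) {
    est <- if (method == "true") {
      if (!"true_h" %in% names(truth)) abort("method = \"true\" needs a `true_h` column.")
      dplyr::rename(truth, h = "true_h")
    } else {
      estimate_hurst(series, method = method, n_strides = s,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, 271L, s))
    }
    g <- grid_for_est(est)
    g$stride_count <- as.integer(s)
    g
  })
  out$method <- toupper(method)
  cols <- intersect(c("group", "variable", "method", "stride_count", "trials_used",
                      "icc", "f_stat", "df1", "df2", "ci_low", "ci_high", "band"),
                    names(out))
  out <- dplyr::select(out, dplyr::all_of(cols))
  class(out) <- c("reliability_grid", class(out))
  out
}
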