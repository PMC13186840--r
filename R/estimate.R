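#' Estimate Hurst exponents for every series in a long-format table
#'
#' Data-frame-first wrapper around [dfa_estimate()] and [hkp_estimate()].
#' The input is a long table with one row per stride (the cohort interchange
#' format: `subject`, `group`, `day`, `trial`, `variable`, `stride`, `value`);
#' each unique combination of the identifier columns is treated as one series
#' and estimated independently. When many HKp series share a length, one
#' posterior grid cache per length is built and reused.
#'
#' @param data Long-format data frame of stride-level values.
#' @param method `"dfa"` or `"hkp"`.
#' @param value Column holding the series values (tidy-selected; default
#'   `value`).
#' @param by Character vector of identifier columns defining one series
#'   (default the standard cohort keys present in `data`).
#' @param n_strides Optional: keep only the final `n_strides` values of each
#'   series before estimating (see [slice_last_strides()]).
#' @param seed Optional integer seed (used by HKp accept-reject; per-series
#'   substreams are derived from it).
#' @param use_cache For HKp, share a posterior grid across equal-length
#'   series (default `TRUE`; exact evaluation when `FALSE`).
#' @return A tibble with the identifier columns, `method`, `n` (series
#'   length) and the point estimate `h`, one row per series.
#' @examples
#' cohort <- generate_cohort(n_subjects = 2, trials_per_day = 2,
#'                           strides_per_trial = 64, seed = 1)
#' estimate_hurst(cohort$series, method = "hkp", seed = 2)
#' @export
estimate_hurst <- function(data, method = c("dfa", "hkp"), value = "value",
                           by = NULL, n_strides = NULL, seed = NULL,
                           use_cache = TRUE) {
  method <- match.arg(tolower(method[1]), c("dfa", "hkp"))
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  by <- by %||% intersect(c("subject", "group", "day", "trial", "variable"),
                          names(data))
  if (!length(by)) abort("no identifier columns found; supply `by`.")
  if (!value %in% names(data)) abort(sprintf("column `%s` not found.", value))

  keys <- dplyr::distinct(dplyr::select(data, dplyr::all_of(by)))
  split_vals <- dplyr::group_split(dplyr::group_by(data, dplyr::across(dplyr::all_of(by))))
  keys <- dplyr::bind_rows(lapply(split_vals, function(g) g[1, by, drop = FALSE]))
  series <- lapply(split_vals, function(g) g[[value]])
  if (!is.null(n_strides)) {
    series <- lapply(series, function(x) slice_last_strides(x, n_strides))
  }
  lens <- lengths(series)

  h <- numeric(length(series))
  if (method == "dfa") {
    for (len in unique(lens)) {
      idx <- which(lens == len)
      X <- matrix(unlist(series[idx]), nrow = len)
      h[idx] <- dfa_matrix(X)$alpha
    }
  } else if (use_cache) {
    for (len in unique(lens)) {
      idx <- which(lens == len)
      cache <- hk_grid_cache(len)
      X <- matrix(unlist(series[idx]), nrow = len)
      h[idx] <- hkp_estimate_matrix(X, cache, seed = seed %||% sample.int(2^31 - 2, 1))
    }
  } else {
    for (i in seq_along(series)) {
      h[i] <- hkp_estimate(series[[i]],
                           seed = if (is.null(seed)) NULL else derive_seed(seed, 811L, i))$point
    }
  }
  out <- tibble::as_tibble(keys)
  out$method <- toupper(method)
  out$n <- as.integer(lens)
  out$h <- h
  out
}
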