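#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a DFA fit into its per-scale table
#'
#' @param x A `dfa_estimate`.
#' @param ... Unused.
#' @return Tibble with `scale`, `fluctuation`, `log_scale`,
#'   `log_fluctuation`, `used`.
#' @export
tidy.dfa_estimate <- function(x, ...) {
  dplyr::mutate(x$fit,
    log_scale = log(.data$scale),
    log_fluctuation = ifelse(.data$used, log(.data$fluctuation), NA_real_),
    .after = "fluctuation"
  )
}

#' @describeIn tidy.dfa_estimate One-row fit summary (`method`, `h` = alpha,
#'   `intercept`, `r_squared`, `n`, `n_scales`).
#' @export
glance.dfa_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method, h = x$point, intercept = x$intercept,
    r_squared = x$r_squared, n = x$n, n_scales = sum(x$fit$used)
  )
}

#' Tidy an HKp estimate into its posterior samples
#'
#' @param x An `hkp_estimate`.
#' @param ... Unused.
#' @return Tibble with `draw` (acceptance order) and `h`.
#' @export
tidy.hkp_estimate <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$samples), h = x$samples)
}

#' @describeIn tidy.hkp_estimate One-row summary (`method`, `h` = median of
#'   samples, `peak_h`, `n_samples`, `n`).
#' @export
glance.hkp_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method, h = x$point, peak_h = x$peak_h,
    n_samples = length(x$samples), n = x$n
  )
}
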