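#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_abline geom_hline geom_ribbon geom_histogram geom_vline labs
#'   scale_fill_manual facet_grid theme_minimal vars
NULL

#' @export
ggplot2::autoplot

#' Log-log fluctuation plot of a DFA fit
#'
#' @param object A `dfa_estimate`.
#' @param ... Unused.
#' @return A ggplot: log F(n) against log n with the fitted line whose slope
#'   is the reported scaling exponent.
#' @export
autoplot.dfa_estimate <- function(object, ...) {
  d <- tidy(object)
  ggplot(d[d$used, ], aes(x = .data$log_scale, y = .data$log_fluctuation)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_abline(slope = object$point, intercept = object$intercept,
                colour = "steelblue") +
    labs(
      x = "log window size n", y = "log F(n)",
      title = sprintf("DFA: alpha = %.3f (R² = %.3f)",
                      object$point, object$r_squared)
    ) +
    theme_minimal()
}

#' Posterior sample histogram of an HKp estimate
#'
#' @param object An `hkp_estimate`.
#' @param ... Unused.
#' @return A ggplot: histogram of the accepted H draws with the posterior
#'   peak and the median point estimate marked.
#' @export
autoplot.hkp_estimate <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$h)) +
    geom_histogram(bins = 15, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$point, colour = "firebrick") +
    geom_vline(xintercept = object$peak_h, colour = "steelblue",
               linetype = "dashed") +
    labs(
      x = "H", y = "accepted draws",
      title = sprintf("HKp: median H = %.3f (peak %.3f)",
                      object$point, object$peak_h)
    ) +
    theme_minimal()
}

#' Heatmap of a between-day reliability grid
#'
#' @param object A `reliability_grid`.
#' @param ... Unused.
#' @return A ggplot heatmap (stride count by trials averaged) coloured by
#'   reliability band, faceted by group/variable when present.
#' @export
autoplot.reliability_grid <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$stride_count, y = .data$trials_used,
                          fill = .data$band)) +
    geom_tile() +
    scale_fill_manual(
      values = c(poor = "#5e4fa2", moderate = "#d53e4f",
                 good = "#fdae61", excellent = "#fee08b"),
      drop = FALSE, na.value = "grey85"
    ) +
    labs(x = "strides per trial", y = "trials averaged", fill = "ICC band",
         title = sprintf("Between-day ICC(3,k), %s", object$method[1])) +
    theme_minimal()
  facets <- intersect(c("group", "variable"), names(object))
  keep <- facets[vapply(facets, function(f) length(unique(object[[f]])) > 1, TRUE)]
  if (length(keep) == 2L) {
    p <- p + facet_grid(rows = vars(.data$variable), cols = vars(.data$group))
  } else if (length(keep) == 1L) {
    p <- p + ggplot2::facet_wrap(keep)
  }
  p
}

#' Power curves over group size
#'
#' @param object A `power_curve` tibble (from [power_curve()] or a bound set
#'   of them).
#' @param ... Unused.
#' @return A ggplot of estimated power against subjects per group with
#'   binomial confidence ribbons, coloured by method, with the 0.8
#'   convention marked.
#' @export
autoplot.power_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$n_per_group, y = .data$power,
                     colour = .data$method, fill = .data$method)) +
    geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                alpha = 0.2, colour = NA) +
    geom_line() +
    geom_point(size = 0.9) +
    geom_hline(yintercept = 0.8, linetype = "dashed") +
    labs(x = "subjects per group", y = "estimated power",
         colour = "method", fill = "method") +
    theme_minimal()
}
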