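#' Read a long-format stride series CSV
#'
#' Reads and validates the interchange format: header
#' `subject,group,day,trial,variable,stride,value`, one row per stride, with
#' stride indices contiguous (step 1) within each trial. Malformed input is
#' rejected with an error naming the offending series.
#'
#' @param path CSV file path.
#' @param variable,group,day Optional filters applied after validation.
#' @return Tibble in the interchange layout.
#' @export
read_series_csv <- function(path, variable = NULL, group = NULL, day = NULL) {
  needed <- c("subject", "group", "day", "trial", "variable", "stride", "value")
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(sprintf("missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  for (col in c("day", "trial", "stride", "value")) {
    if (!is.numeric(data[[col]])) {
      abort(sprintf("column `%s` must be numeric.", col))
    }
  }
  if (anyNA(data$value)) abort("column `value` contains missing or non-numeric entries.")
  bad <- data |>
    dplyr::group_by(.data$subject, .data$group, .data$day, .data$trial,
                    .data$variable) |>
    dplyr::summarise(
      contiguous = all(diff(sort(.data$stride)) == 1L), .groups = "drop"
    ) |>
    dplyr::filter(!.data$contiguous)
  if (nrow(bad)) {
    b <- bad[1, ]
    abort(sprintf(
      "non-contiguous stride indices for subject %s, day %s, trial %s, variable %s.",
      b$subject, b$day, b$trial, b$variable
    ))
  }
  if (!is.null(variable)) data <- data[data$variable %in% variable, ]
  if (!is.null(group)) data <- data[data$group %in% group, ]
  if (!is.null(day)) data <- data[data$day %in% day, ]
  dplyr::arrange(tibble::as_tibble(data), .data$subject, .data$variable,
                 .data$day, .data$trial, .data$stride)
}

#' Write tidy results to CSV or JSON
#'
#' One record per row; numeric columns are written at 10 significant digits
#' so files round-trip within write precision. An empty table produces a
#' header-only CSV (or empty JSON array).
#'
#' @param x Data frame of results.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `x`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x))
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.factor), as.character
  ))
  if (format == "csv") {
    rounded <- dplyr::mutate(x, dplyr::across(
      dplyr::where(is.double), ~ signif(.x, 10)
    ))
    readr::write_csv(rounded, path, progress = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = 10, pretty = TRUE)
  }
  invisible(x)
}

#' Read a run configuration file
#'
#' Reads a YAML (or JSON) key-value configuration for batch runs: master
#' seed, replicate counts, grid specifications, method options and paths.
#' Values given in `overrides` replace file values, mirroring CLI flags.
#'
#' @param path Configuration file (`.yaml`/`.yml`/`.json`).
#' @param overrides Named list of values replacing file entries.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required to read YAML configs.")
    }
    yaml::read_yaml(path)
  }
  utils::modifyList(as.list(cfg), as.list(overrides))
}
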