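#' Generate a synthetic multi-day gait cohort
#'
#' Builds a long-format synthetic cohort emulating the structure of
#' multi-day overground walking studies: several age groups, two collection
#' days, nine trials per day, and at least 173 strides per trial. Each
#' subject-day-trial carries a true Hurst exponent assembled from additive
#' Gaussian variance components
#' \deqn{H_{idt} = \mu_g + b_i + w_{id} + e_{idt}}
#' (subject, subject-day, and trial levels), truncated to (0, 1) by
#' subject-wise rejection-resampling; the realized trial series is an exact
#' fGn draw at that true H. The true values are returned alongside the
#' series so that design properties (e.g. the between-day ICC implied by the
#' variance components, see [expected_day_icc()]) can be verified directly.
#'
#' @param n_subjects Subjects per group. Scalar or vector matching `groups`.
#' @param groups Character vector of group labels.
#' @param group_mean_h Mean true H per group (recycled).
#' @param days Number of days (default 2).
#' @param trials_per_day Trials per subject per day (default 9).
#' @param strides_per_trial Strides per trial (default 173).
#' @param variables Variable names; each variable receives its own
#'   independent true-H draw and series.
#' @param between_subject_sd,between_day_sd,between_trial_sd Standard
#'   deviations of the subject, subject-day and residual trial components of
#'   true H.
#' @param series_sd Marginal SD of the simulated series values (default 1;
#'   Hurst estimators are scale invariant).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return Object of class `hurst_cohort`: list with `series` (tibble
#'   `subject, group, day, trial, variable, stride, value`), `truth` (tibble
#'   `subject, group, day, trial, variable, true_h`), `n_resampled`
#'   (subject-variable H vectors redrawn during truncation) and the call
#'   parameters in `config`.
#' @examples
#' coh <- generate_cohort(n_subjects = 3, trials_per_day = 2,
#'                        strides_per_trial = 64, seed = 1)
#' @export
generate_cohort <- function(n_subjects = c(34, 57, 38),
                            groups = c("young", "middle", "older"),
                            group_mean_h = 0.75,
                            days = 2, trials_per_day = 9,
                            strides_per_trial = 173,
                            variables = "stride_interval",
                            between_subject_sd = 0.089,
                            between_day_sd = 0.02,
                            between_trial_sd = 0.065,
                            series_sd = 1,
                            seed = NULL) {
  if (length(n_subjects) == 1L) n_subjects <- rep(n_subjects, length(groups))
  if (length(n_subjects) != length(groups)) {
    abort("`n_subjects` must be scalar or match `groups` in length.")
  }
  group_mean_h <- rep_len(group_mean_h, length(groups))
  for (mu in group_mean_h) assert_scalar_prob(mu, "group_mean_h")
  if (strides_per_trial < 8) abort("`strides_per_trial` must be at least 8.")
  if (any(c(between_subject_sd, between_day_sd, between_trial_sd) < 0)) {
    abort("variance-component standard deviations must be nonnegative.")
  }
  seed <- seed %||% sample.int(2^31 - 2, 1)

  n_trial_cells <- days * trials_per_day
  truth_rows <- list()
  series_rows <- list()
  n_resampled <- 0L
  subj_counter <- 0L
  for (g in seq_along(groups)) {
    for (i in seq_len(n_subjects[g])) {
      subj_counter <- subj_counter + 1L
      subj_id <- sprintf("S%03d", subj_counter)
      for (v in seq_along(variables)) {
        # true H vector for all day x trial cells of this subject-variable,
        # redrawn wholesale until every entry lies in (0, 1)
        hvec <- with_seed_(derive_seed(seed, 101L, g, i, v), {
          repeat_draws <- -1L
          repeat {
            repeat_draws <- repeat_draws + 1L
            b <- rnorm(1, 0, between_subject_sd)
            w <- rnorm(days, 0, between_day_sd)
            e <- rnorm(n_trial_cells, 0, between_trial_sd)
            h <- group_mean_h[g] + b + rep(w, each = trials_per_day) + e
            if (all(h > 0 & h < 1)) break
            if (repeat_draws > 1e5) abort("cohort true-H resampling failed to terminate.")
          }
          attr(h, "redraws") <- repeat_draws
          h
        })
        n_resampled <- n_resampled + attr(hvec, "redraws")
        cell <- 0L
        for (d in seq_len(days)) {
          for (tr in seq_len(trials_per_day)) {
            cell <- cell + 1L
            x <- simulate_fgn(hvec[cell], strides_per_trial, sd = series_sd,
                              seed = derive_seed(seed, 202L, g, i, v, d, tr))
            truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
              subject = subj_id, group = groups[g], day = d, trial = tr,
              variable = variables[v], true_h = hvec[cell]
            )
            series_rows[[length(series_rows) + 1L]] <- tibble::tibble(
              subject = subj_id, group = groups[g], day = d, trial = tr,
              variable = variables[v], stride = seq_len(strides_per_trial),
              value = x
            )
          }
        }
      }
    }
  }
  structure(
    list(
      series = dplyr::bind_rows(series_rows),
      truth = dplyr::bind_rows(truth_rows),
      n_resampled = n_resampled,
      config = list(
        n_subjects = n_subjects, groups = groups, group_mean_h = group_mean_h,
        days = days, trials_per_day = trials_per_day,
        strides_per_trial = strides_per_trial, variables = variables,
        between_subject_sd = between_subject_sd, between_day_sd = between_day_sd,
        between_trial_sd = between_trial_sd, series_sd = series_sd, seed = seed
      )
    ),
    class = "hurst_cohort"
  )
}

#' @export
print.hurst_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<hurst_cohort: %d subjects in %d group(s), %d day(s) x %d trial(s), %d strides/trial>\n",
    sum(cfg$n_subjects), length(cfg$groups), cfg$days, cfg$trials_per_day,
    cfg$strides_per_trial
  ))
  cat(sprintf("  variables: %s; seed %d; %d truncation redraws\n",
              paste(cfg$variables, collapse = ", "), cfg$seed, x$n_resampled))
  invisible(x)
}

#' Between-day ICC implied by cohort variance components
#'
#' Closed-form design value of the between-day consistency ICC(3,2) of true
#' H when day values are averages of `k_trials` trials: with subject
#' variance \eqn{\sigma_b^2}, subject-day variance \eqn{\sigma_w^2} and
#' trial variance \eqn{\sigma_e^2}, the day-average of a subject has
#' between-day-replicate variance \eqn{\sigma_w^2 + \sigma_e^2 / k}, so
#' \deqn{ICC(3,2) = \frac{\sigma_b^2}{\sigma_b^2 + (\sigma_w^2 + \sigma_e^2/k)/2}.}
#' Useful for choosing components that target a given design reliability
#' (truncation to (0,1) perturbs this only marginally for the defaults).
#'
#' @param between_subject_sd,between_day_sd,between_trial_sd Component SDs.
#' @param k_trials Trials averaged per day.
#' @return The design ICC value.
#' @export
expected_day_icc <- function(between_subject_sd, between_day_sd,
                             between_trial_sd, k_trials = 1) {
  vb <- between_subject_sd^2
  vw <- between_day_sd^2 + between_trial_sd^2 / k_trials
  vb / (vb + vw / 2)
}

#' Write a cohort to interchange CSV files
#'
#' Writes the long-format series table and the companion truth table using
#' the standard headers `subject,group,day,trial,variable,stride,value` and
#' `subject,group,day,trial,variable,true_h`. Output is deterministic, so a
#' fixed-seed cohort round-trips byte-identically.
#'
#' @param cohort A `hurst_cohort`.
#' @param series_path,truth_path Output file paths (`truth_path = NULL`
#'   skips the truth file).
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, series_path, truth_path = NULL) {
  if (!inherits(cohort, "hurst_cohort")) abort("`cohort` must be a hurst_cohort.")
  readr::write_csv(cohort$series, series_path, progress = FALSE)
  if (!is.null(truth_path)) readr::write_csv(cohort$truth, truth_path, progress = FALSE)
  invisible(cohort)
}
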