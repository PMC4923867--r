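# internal: check a reproduction-trial table and return it as a tibble
check_trials <- function(trials, require_cols = c("stimulus_ms", "reproduced_ms")) {
  if (!is.data.frame(trials)) {
    stop_timeprior("SCHEMA", "`trials` must be a data frame of reproduction trials.")
  }
  missing_cols <- setdiff(require_cols, names(trials))
  if (length(missing_cols) > 0) {
    stop_timeprior("SCHEMA", sprintf(
      "`trials` is missing required column(s): %s.",
      paste(missing_cols, collapse = ", ")))
  }
  as_tibble(trials)
}

#' Fit the reproduction line
#'
#' Ordinary least-squares fit of reproduced duration on presented duration —
#' the "linear fits of the data" whose slope carries the central-tendency
#' signal.
#'
#' @param trials A data frame with columns `stimulus_ms` and `reproduced_ms`
#'   (at least two distinct stimulus values).
#' @return A one-row tibble with `slope`, `intercept_ms`, `n_trials`.
#' @examples
#' toy <- tibble::tibble(stimulus_ms = c(1000, 1200, 1400),
#'                       reproduced_ms = c(1100, 1200, 1300))
#' fit_reproduction_line(toy) # slope 0.5, intercept 600
#' @export
fit_reproduction_line <- function(trials) {
  trials <- check_trials(trials)
  if (length(unique(trials$stimulus_ms)) < 2L) {
    stop_timeprior("DOMAIN",
                   "at least two distinct stimulus values are needed to fit a slope.")
  }
  fit <- lm(reproduced_ms ~ stimulus_ms, data = trials)
  tibble(slope = unname(coef(fit)[2L]), intercept_ms = unname(coef(fit)[1L]),
         n_trials = nrow(trials))
}

#' Regression index of a session
#'
#' One minus the OLS slope of reproduced on presented duration: 0 for
#' veridical reproduction, 1 for complete regression to the mean. Adding a
#' constant offset to every response leaves it unchanged (systematic bias is
#' absorbed by the intercept).
#'
#' @inheritParams fit_reproduction_line
#' @return A single number.
#' @examples
#' veridical <- tibble::tibble(stimulus_ms = c(1000, 1200, 1400),
#'                             reproduced_ms = c(1000, 1200, 1400))
#' regression_index(veridical) # 0
#' @export
regression_index <- function(trials) {
  1 - fit_reproduction_line(trials)$slope
}

#' BIAS / CV partition of reproduction error
#'
#' Splits total reproduction error into orthogonal accuracy and reliability
#' components, each normalised by a duration scale (default: the mean of the
#' session's stimulus set). `BIAS` is the root-mean-square over stimuli of
#' the deviation of the mean reproduction from the stimulus; `CV` is the
#' root-mean-square over stimuli of the within-stimulus response SD; and
#' `total_error = sqrt(BIAS^2 + CV^2)` by construction.
#'
#' @inheritParams fit_reproduction_line
#' @param normaliser_ms Positive duration used to normalise both components;
#'   defaults to the mean of the distinct stimulus values. A smaller
#'   normaliser inflates both components.
#' @return A one-row tibble with `bias`, `cv`, `total_error`.
#' @examples
#' trials <- simulate_reproduction(observer_params(400, 0.36),
#'                                 build_paradigm()$short, seed = 2)
#' error_components(trials)
#' @export
error_components <- function(trials, normaliser_ms = NULL) {
  trials <- check_trials(trials)
  normaliser_ms <- normaliser_ms %||% mean(unique(trials$stimulus_ms))
  assert_number(normaliser_ms, "normaliser_ms", lower = 0, allow_boundary = FALSE)
  per_stim <- trials |>
    dplyr::summarise(n = dplyr::n(), m = mean(.data$reproduced_ms),
                     v = var(.data$reproduced_ms), .by = "stimulus_ms")
  if (any(per_stim$n < 2L)) {
    stop_timeprior("DOMAIN",
                   "every stimulus needs at least two trials for the CV component.")
  }
  bias <- sqrt(mean((per_stim$m - per_stim$stimulus_ms)^2)) / normaliser_ms
  cv <- sqrt(mean(per_stim$v)) / normaliser_ms
  tibble(bias = bias, cv = cv, total_error = sqrt(bias^2 + cv^2))
}

#' Per-session measures for trial tables
#'
#' Convenience wrapper computing the full measurement set — slope, intercept,
#' regression index, BIAS, CV, total error — grouped by whichever of
#' `participant_id` and `session` are present in the input.
#'
#' @inheritParams error_components
#' @return A tibble with one row per group and columns `slope`,
#'   `intercept_ms`, `regression_index`, `bias`, `cv`, `total_error`.
#' @examples
#' cohort <- generate_cohort(cohort_spec("demo", 2, wf_mean = 0.36, seed = 5))
#' session_measures(cohort$trials)
#' @export
session_measures <- function(trials, normaliser_ms = NULL) {
  trials <- check_trials(trials)
  by <- intersect(c("participant_id", "group", "session"), names(trials))
  one <- function(df) {
    line <- fit_reproduction_line(df)
    err <- error_components(df, normaliser_ms)
    tibble(slope = line$slope, intercept_ms = line$intercept_ms,
           regression_index = 1 - line$slope, bias = err$bias, cv = err$cv,
           total_error = err$total_error)
  }
  if (length(by) == 0) return(one(trials))
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Context dependency on common stimuli
#'
#' Mean difference between long- and short-session reproductions of the
#' stimuli the two sessions (nearly) share. In the default paradigm the
#' overlapping grids are offset by 1 ms (e.g. 1271 vs 1270 ms), so stimuli
#' are matched within a tolerance.
#'
#' @param short_trials,long_trials Trial tables for the two sessions.
#' @param match_tolerance_ms Maximum stimulus difference for a pair to count
#'   as the same duration (default 5 ms).
#' @return Mean difference in ms (long minus short) over the matched stimuli;
#'   positive when the long session pulls reproductions upward.
#' @examples
#' p <- observer_params(400, 0.36)
#' trials <- simulate_reproduction(p, build_paradigm(), seed = 4)
#' context_dependency(dplyr::filter(trials, session == "short"),
#'                    dplyr::filter(trials, session == "long"))
#' @export
context_dependency <- function(short_trials, long_trials,
                               match_tolerance_ms = 5) {
  short_trials <- check_trials(short_trials)
  long_trials <- check_trials(long_trials)
  assert_number(match_tolerance_ms, "match_tolerance_ms", lower = 0)
  s_means <- short_trials |>
    dplyr::summarise(m = mean(.data$reproduced_ms), .by = "stimulus_ms")
  l_means <- long_trials |>
    dplyr::summarise(m = mean(.data$reproduced_ms), .by = "stimulus_ms")
  pairs <- tidyr::expand_grid(s = seq_len(nrow(s_means)),
                              l = seq_len(nrow(l_means))) |>
    dplyr::mutate(gap = abs(s_means$stimulus_ms[.data$s] -
                              l_means$stimulus_ms[.data$l])) |>
    dplyr::filter(.data$gap <= match_tolerance_ms) |>
    dplyr::slice_min(.data$gap, by = "s", with_ties = FALSE)
  if (nrow(pairs) == 0) {
    stop_timeprior("DOMAIN", "no stimuli match across sessions within the tolerance.")
  }
  mean(l_means$m[pairs$l] - s_means$m[pairs$s])
}

#' Split-half regression indices
#'
#' Regression index computed separately on the first and second halves of a
#' session (split by presentation order; an odd trial count puts the extra
#' trial in the first half). A growing second-half index is the signature of
#' a prior building up during the session; the stationary simulator produces
#' matching halves up to Monte-Carlo noise.
#'
#' @param trials A trial table with a `trial_index` column.
#' @return A tibble with columns `half` (`"first"`, `"second"`) and
#'   `regression_index`.
#' @examples
#' trials <- simulate_reproduction(observer_params(400, 0.36),
#'                                 build_paradigm()$short, seed = 6)
#' split_half_regression(trials)
#' @export
split_half_regression <- function(trials) {
  trials <- check_trials(trials, c("trial_index", "stimulus_ms", "reproduced_ms"))
  trials <- dplyr::arrange(trials, .data$trial_index)
  n <- nrow(trials)
  if (n < 4L) {
    stop_timeprior("DOMAIN", "at least four trials are needed for a split-half analysis.")
  }
  cut <- ceiling(n / 2)
  halves <- list(first = trials[seq_len(cut), ],
                 second = trials[(cut + 1L):n, ])
  for (h in names(halves)) {
    if (length(unique(halves[[h]]$stimulus_ms)) < 2L) {
      stop_timeprior("DOMAIN", sprintf(
        "the %s half has fewer than two distinct stimuli.", h))
    }
  }
  tibble(half = names(halves),
         regression_index = unname(purrr::map_dbl(halves, regression_index)))
}

#' Cohen's d from group summaries
#'
#' Standardised mean difference using the pooled standard deviation,
#' `d = (m1 - m2) / sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param m1,sd1,n1 Mean, SD and size of the first group.
#' @param m2,sd2,n2 Mean, SD and size of the second group.
#' @return A single number.
#' @examples
#' cohens_d(0.36, 0.21, 23, 0.22, 0.13, 23) # ~0.80
#' @export
cohens_d <- function(m1, sd1, n1, m2, sd2, n2) {
  assert_number(m1, "m1"); assert_number(m2, "m2")
  assert_number(sd1, "sd1", lower = 0); assert_number(sd2, "sd2", lower = 0)
  n1 <- assert_count(n1, "n1", lower = 2L)
  n2 <- assert_count(n2, "n2", lower = 2L)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) {
    stop_timeprior("DOMAIN", "pooled standard deviation is zero; d is undefined.")
  }
  (m1 - m2) / pooled
}
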