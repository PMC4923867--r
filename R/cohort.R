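#' Specify a synthetic observer cohort
#'
#' Describes a group of simulated participants. Weber fractions and prior
#' widths are drawn from normal distributions truncated at zero (a
#' participant-heterogeneity model; set the SDs to 0 for a homogeneous
#' group), and the constant response bias from an untruncated normal.
#'
#' @param group_label Group name (e.g. `"autistic"`, `"comparison"`).
#' @param n_participants Number of simulated participants (>= 1).
#' @param wf_mean,wf_sd Mean and SD of the truncated-normal Weber-fraction
#'   distribution.
#' @param prior_width_mean_ms,prior_width_sd_ms Mean and SD (ms) of the
#'   truncated-normal prior-width distribution.
#' @param motor_noise_coef Motor-noise coefficient shared by the group
#'   (default 0.05).
#' @param bias_mean_ms,bias_sd_ms Mean and SD (ms) of the constant response
#'   offset (default 0, 0: the pure model).
#' @param seed Integer seed for cohort generation.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec("autistic", 23, wf_mean = 0.36, wf_sd = 0.21,
#'             prior_width_mean_ms = 400, prior_width_sd_ms = 50, seed = 11)
#' @export
cohort_spec <- function(group_label, n_participants, wf_mean, wf_sd = 0,
                        prior_width_mean_ms = 400, prior_width_sd_ms = 0,
                        motor_noise_coef = 0.05, bias_mean_ms = 0,
                        bias_sd_ms = 0, seed = 1L) {
  if (!is.character(group_label) || length(group_label) != 1L ||
      !nzchar(group_label)) {
    stop_timeprior("CONFIG", "`group_label` must be a non-empty string.")
  }
  n_participants <- assert_count(n_participants, "n_participants")
  assert_number(wf_mean, "wf_mean")
  assert_number(wf_sd, "wf_sd", lower = 0)
  assert_number(prior_width_mean_ms, "prior_width_mean_ms")
  assert_number(prior_width_sd_ms, "prior_width_sd_ms", lower = 0)
  assert_number(motor_noise_coef, "motor_noise_coef", lower = 0)
  assert_number(bias_mean_ms, "bias_mean_ms")
  assert_number(bias_sd_ms, "bias_sd_ms", lower = 0)
  seed <- assert_count(seed, "seed", lower = 0L)
  # refuse distributions whose untruncated mass is mostly negative: the
  # truncated draw would no longer resemble the nominal (mean, sd)
  if ((wf_sd == 0 && wf_mean < 0) || (wf_sd > 0 && pnorm(0, wf_mean, wf_sd) > 0.5)) {
    stop_timeprior("CONFIG",
                   "`wf_mean`/`wf_sd` put more than half their mass below zero.")
  }
  if ((prior_width_sd_ms == 0 && prior_width_mean_ms <= 0) ||
      (prior_width_sd_ms > 0 && pnorm(0, prior_width_mean_ms, prior_width_sd_ms) > 0.5)) {
    stop_timeprior("CONFIG",
                   "`prior_width_mean_ms`/`prior_width_sd_ms` put more than half their mass at or below zero.")
  }
  structure(
    list(group_label = group_label, n_participants = n_participants,
         wf_mean = wf_mean, wf_sd = wf_sd,
         prior_width_mean_ms = prior_width_mean_ms,
         prior_width_sd_ms = prior_width_sd_ms,
         motor_noise_coef = motor_noise_coef, bias_mean_ms = bias_mean_ms,
         bias_sd_ms = bias_sd_ms, seed = seed),
    class = "cohort_spec")
}

# internal: normal truncated at a strictly positive floor by rejection
rtruncnorm_pos <- function(n, mean, sd, floor = 0) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= floor)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= floor]
  }
  out
}

#' Generate a synthetic cohort on the reproduction paradigm
#'
#' Draws per-participant true parameters from the spec's distributions and
#' simulates each participant through both reproduction sessions and a 2AFC
#' time-discrimination block, recording the true parameters alongside so that
#' estimator-recovery checks can compare against them.
#'
#' @param spec A [cohort_spec()].
#' @param design A [paradigm_design][build_paradigm()] (default paradigm).
#' @param n_discrimination_trials 2AFC trials per participant (default 54).
#' @param reference_ms 2AFC reference duration (default 500 ms).
#' @return An object of class `timing_cohort`: a list of tibbles
#'   `participants` (`participant_id, group, true_wf, true_prior_width_ms,
#'   true_bias_ms, motor_noise_coef`), `trials` (reproduction trials with
#'   `participant_id` and `group` prepended) and `discrimination`.
#' @examples
#' spec <- cohort_spec("demo", 3, wf_mean = 0.36, seed = 7)
#' cohort <- generate_cohort(spec)
#' dplyr::count(cohort$trials, participant_id, session)
#' @export
generate_cohort <- function(spec, design = build_paradigm(),
                            n_discrimination_trials = 54, reference_ms = 500) {
  if (!inherits(spec, "cohort_spec")) {
    stop_timeprior("CONFIG", "`spec` must be a cohort_spec object.")
  }
  if (!inherits(design, "paradigm_design")) {
    stop_timeprior("DOMAIN", "`design` must be a paradigm_design.")
  }
  n <- spec$n_participants
  withr::with_seed(spec$seed, {
    truth <- tibble(
      participant_id = sprintf("%s_%02d", spec$group_label, seq_len(n)),
      group = spec$group_label,
      true_wf = pmax(rtruncnorm_pos(n, spec$wf_mean, spec$wf_sd), 0),
      true_prior_width_ms = rtruncnorm_pos(n, spec$prior_width_mean_ms,
                                           spec$prior_width_sd_ms),
      true_bias_ms = rnorm(n, spec$bias_mean_ms, spec$bias_sd_ms),
      motor_noise_coef = spec$motor_noise_coef)
    sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n),
                        nrow = n)
  })
  trials <- purrr::pmap(truth, function(participant_id, group, true_wf,
                                        true_prior_width_ms, true_bias_ms,
                                        motor_noise_coef) {
    i <- match(participant_id, truth$participant_id)
    params <- observer_params(prior_width_ms = true_prior_width_ms,
                              weber_fraction = true_wf,
                              motor_noise_coef = motor_noise_coef,
                              constant_bias_ms = true_bias_ms)
    simulate_reproduction(params, design, seed = sub_seeds[i, 1L]) |>
      dplyr::mutate(participant_id = participant_id, group = group,
                    .before = 1)
  }) |> dplyr::bind_rows()
  disc <- purrr::map(seq_len(n), function(i) {
    wf_i <- truth$true_wf[i]
    if (wf_i <= 0) return(NULL)
    generate_discrimination_data(wf_i, reference_ms = reference_ms,
                                 n_trials = n_discrimination_trials,
                                 seed = sub_seeds[i, 2L]) |>
      dplyr::mutate(participant_id = truth$participant_id[i],
                    group = truth$group[i], .before = 1)
  }) |> dplyr::bind_rows()
  structure(list(participants = truth, trials = trials, discrimination = disc),
            class = "timing_cohort")
}

#' @export
print.timing_cohort <- function(x, ...) {
  cat(sprintf("<timing_cohort> %d participants (%s), %d reproduction trials, %d discrimination trials\n",
              nrow(x$participants),
              paste(unique(x$participants$group), collapse = ", "),
              nrow(x$trials), nrow(x$discrimination)))
  invisible(x)
}

#' Generate 2AFC time-discrimination data
#'
#' Simulates a two-alternative forced-choice block against a fixed reference.
#' Comparison durations sit on a fixed symmetric grid of `n_levels` values
#' spanning `span_sd` psychometric SDs (`placement_wf * reference_ms`) either
#' side of the reference, capped so every comparison stays positive; the grid
#' is tiled over trials and shuffled. Each response is drawn from a
#' cumulative-Gaussian psychometric function with SD
#' `weber_fraction * reference_ms`.
#'
#' @param weber_fraction True Weber fraction of the simulated observer (> 0).
#' @param reference_ms Reference duration, ms (default 500).
#' @param n_trials Number of trials (default 54, two interleaved blocks of 27).
#' @param n_levels Number of fixed comparison levels (default 9).
#' @param span_sd Half-width of the grid in psychometric SDs (default 3).
#' @param placement_wf Weber fraction used to place the grid (defaults to
#'   `weber_fraction`; pass a nominal design value to decouple placement from
#'   the simulated observer).
#' @param seed Integer seed.
#' @return A tibble with columns `trial_index`, `reference_ms`,
#'   `comparison_ms`, `chose_comparison_longer`.
#' @examples
#' generate_discrimination_data(0.36, n_trials = 54, seed = 3)
#' @export
generate_discrimination_data <- function(weber_fraction, reference_ms = 500,
                                         n_trials = 54, n_levels = 9,
                                         span_sd = 3,
                                         placement_wf = weber_fraction,
                                         seed = 1L) {
  assert_number(weber_fraction, "weber_fraction", lower = 0,
                allow_boundary = FALSE)
  assert_number(reference_ms, "reference_ms", lower = 0, allow_boundary = FALSE)
  n_trials <- assert_count(n_trials, "n_trials")
  n_levels <- assert_count(n_levels, "n_levels", lower = 2L)
  assert_number(span_sd, "span_sd", lower = 0, allow_boundary = FALSE)
  assert_number(placement_wf, "placement_wf", lower = 0, allow_boundary = FALSE)
  seed <- assert_count(seed, "seed", lower = 0L)
  span <- min(span_sd * placement_wf * reference_ms, 0.9 * reference_ms)
  levels <- reference_ms + seq(-span, span, length.out = n_levels)
  withr::with_seed(seed, {
    comparison <- sample(rep_len(levels, n_trials))
    p_longer <- pnorm(comparison, mean = reference_ms,
                      sd = weber_fraction * reference_ms)
    chose <- stats::runif(n_trials) < p_longer
  })
  tibble(trial_index = seq_len(n_trials), reference_ms = reference_ms,
         comparison_ms = comparison, chose_comparison_longer = chose)
}
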