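#' Run the simulation stage of the pipeline
#'
#' Generates every cohort in the configuration on the configured paradigm and
#' writes `participants.csv`, `trials.csv` and `discrimination.csv` to the
#' output directory. Reruns with the same configuration are byte-identical.
#'
#' @param config A [run_config][read_run_config()] (or a raw list, validated
#'   on the way in).
#' @param out_dir Output directory (default: the config's `output_dir`).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  config <- ensure_config(config)
  out_dir <- out_dir %||% config$output_dir
  if (length(config$cohort_specs) == 0) {
    stop_timeprior("CONFIG", "config defines no cohorts to simulate.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_timeprior("IO", sprintf("cannot create output directory '%s'.", out_dir))
  }
  cohorts <- purrr::map(config$cohort_specs, generate_cohort,
                        design = config$paradigm_design)
  participants <- dplyr::bind_rows(purrr::map(cohorts, "participants"))
  trials <- dplyr::bind_rows(purrr::map(cohorts, "trials"))
  discrimination <- dplyr::bind_rows(purrr::map(cohorts, "discrimination"))
  paths <- list(participants = file.path(out_dir, "participants.csv"),
                trials = file.path(out_dir, "trials.csv"),
                discrimination = file.path(out_dir, "discrimination.csv"))
  readr::write_csv(participants, paths$participants)
  write_trials_csv(trials, paths$trials)
  readr::write_csv(discrimination, paths$discrimination)
  log_stage("simulate", seed = config$seed, config_hash = rlang::hash(unclass(config)),
            participants = nrow(participants), trials = nrow(trials),
            discrimination = nrow(discrimination))
  invisible(paths)
}

#' Run the analysis stage of the pipeline
#'
#' Reads trial tables (as written by [run_simulate()] or conforming to the
#' same contract), computes per-participant, per-session measures, estimates
#' each participant's Weber fraction from the discrimination data when
#' available (flagging participants whose estimate falls outside `[0, 1]` as
#' excluded), summarises measures by group, derives each group's prior width
#' from its mean regression index and Weber fraction, and computes Cohen's d
#' between every pair of groups. Writes `measures.csv` and
#' `group_summary.json`.
#'
#' @param trials_path Path to a reproduction-trials CSV.
#' @param config A [run_config][read_run_config()] or raw list.
#' @param discrimination_path Optional path to a discrimination CSV.
#' @param out_dir Output directory.
#' @return Invisibly, a list with elements `measures` (tibble) and `summary`
#'   (the group-summary list written as JSON).
#' @export
run_analyze <- function(trials_path, config, discrimination_path = NULL,
                        out_dir = NULL) {
  config <- ensure_config(config)
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials <- read_trials_csv(trials_path)
  measures <- session_measures(trials, config$analysis$normaliser_ms)
  if (config$analysis$split_half && "trial_index" %in% names(trials)) {
    by <- intersect(c("participant_id", "session"), names(trials))
    halves <- trials |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(~ split_half_regression(.x)) |>
      dplyr::ungroup() |>
      tidyr::pivot_wider(names_from = "half",
                         values_from = "regression_index",
                         names_prefix = "regression_index_")
    measures <- dplyr::left_join(measures, halves, by = by)
  }
  wf_by_participant <- NULL
  if (!is.null(discrimination_path)) {
    disc <- read_discrimination_csv(discrimination_path)
    if (!"participant_id" %in% names(disc)) {
      stop_timeprior("SCHEMA",
                     "discrimination data need a `participant_id` column for analysis.")
    }
    wf_by_participant <- disc |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::group_modify(~ tibble(weber_fraction = tryCatch(
        weber_fraction_from_2afc(.x),
        timeprior_error = function(e) NA_real_))) |>
      dplyr::ungroup() |>
      dplyr::mutate(excluded = is.na(.data$weber_fraction) |
                      .data$weber_fraction < 0 | .data$weber_fraction > 1)
    measures <- dplyr::left_join(measures, wf_by_participant,
                                 by = "participant_id")
  }
  t_bar <- paradigm_mean_stimulus(config$paradigm_design)
  grouping <- if ("group" %in% names(measures)) "group" else character()
  participant_level <- if ("participant_id" %in% names(measures)) {
    # average the two sessions per participant before group summaries
    num_vars <- names(measures)[vapply(measures, is.numeric, logical(1))]
    averaged <- measures |>
      dplyr::summarise(dplyr::across(dplyr::all_of(num_vars), mean),
                       .by = dplyr::all_of(c(grouping, "participant_id")))
    if ("excluded" %in% names(measures)) {
      flags <- measures |>
        dplyr::summarise(excluded = any(.data$excluded %in% TRUE),
                         .by = "participant_id")
      averaged <- dplyr::left_join(averaged, flags, by = "participant_id")
    }
    averaged
  } else {
    measures
  }
  if ("excluded" %in% names(participant_level)) {
    participant_level <- dplyr::filter(participant_level,
                                       !(.data$excluded %in% TRUE))
  }
  summarise_measure <- function(df, var) {
    df |>
      dplyr::summarise(n = sum(is.finite(.data[[var]])),
                       mean = mean(.data[[var]], na.rm = TRUE),
                       sd = sd(.data[[var]], na.rm = TRUE),
                       .by = dplyr::all_of(grouping))
  }
  vars <- intersect(c("regression_index", "bias", "cv", "total_error",
                      "weber_fraction"), names(participant_level))
  group_stats <- purrr::map(setNames(vars, vars),
                            ~ summarise_measure(participant_level, .x))
  prior_widths <- NULL
  effect_sizes <- NULL
  if (length(grouping) == 1 && "weber_fraction" %in% vars) {
    joint <- dplyr::left_join(group_stats$regression_index,
                              group_stats$weber_fraction,
                              by = "group", suffix = c("_r", "_wf"))
    prior_widths <- joint |>
      dplyr::mutate(prior_width_ms = purrr::map2_dbl(
        .data$mean_r, .data$mean_wf,
        ~ tryCatch(prior_width_from_regression(.x, .y, t_bar),
                   timeprior_error = function(e) NA_real_)))
    gr <- group_stats$regression_index
    if (nrow(gr) >= 2) {
      pairs <- utils::combn(gr$group, 2, simplify = FALSE)
      effect_sizes <- purrr::map(setNames(vars, vars), function(v) {
        gs <- group_stats[[v]]
        purrr::map_dfr(pairs, function(pr) {
          a <- gs[gs$group == pr[1], ]
          b <- gs[gs$group == pr[2], ]
          tibble(group_1 = pr[1], group_2 = pr[2],
                 cohens_d = cohens_d(a$mean, a$sd, a$n, b$mean, b$sd, b$n))
        })
      })
    }
  }
  summary <- list(
    seed = config$seed,
    mean_stimulus_ms = t_bar,
    group_summaries = group_stats,
    prior_widths = prior_widths,
    effect_sizes = effect_sizes)
  paths <- list(measures = file.path(out_dir, "measures.csv"),
                summary = file.path(out_dir, "group_summary.json"))
  readr::write_csv(measures, paths$measures)
  jsonlite::write_json(
    list(seed = config$seed, mean_stimulus_ms = t_bar,
         group_summaries = group_stats, prior_widths = prior_widths,
         effect_sizes = effect_sizes),
    paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  log_stage("analyze", seed = config$seed, input = basename(trials_path),
            input_hash = unname(tools::md5sum(trials_path)),
            measures = nrow(measures))
  invisible(list(measures = measures, summary = summary, paths = paths))
}

#' Run the landscape stage of the pipeline
#'
#' Builds the relative-error landscape from the configuration's `landscape`
#' block and writes it as a long-form CSV (`wf, prior_width_ms,
#' raw_total_error, relative_error`) with a JSON sidecar recording the
#' settings. When group points are supplied (label, regression index, Weber
#' fraction — e.g. from [run_analyze()]'s prior-width table), they are placed
#' on the surface and written to `group_points.json`; with `figure: true` in
#' the config a heat-map PNG is also saved.
#'
#' @param config A [run_config][read_run_config()] or raw list.
#' @param out_dir Output directory.
#' @param groups Optional data frame with `label`, `regression_index`, `wf`.
#' @return Invisibly, a list with the `landscape` object, `points` (or NULL)
#'   and written paths.
#' @export
run_landscape <- function(config, out_dir = NULL, groups = NULL) {
  config <- ensure_config(config)
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lb <- config$landscape
  land <- relative_error_landscape(
    config$paradigm_design, wf_grid = lb$wf_grid,
    prior_grid_ms = lb$prior_grid_ms, reps = lb$reps, seed = config$seed,
    normalisation = lb$normalisation)
  paths <- list(landscape = file.path(out_dir, "landscape.csv"),
                meta = file.path(out_dir, "landscape_meta.json"))
  readr::write_csv(dplyr::select(land$grid, "wf", "prior_width_ms",
                                 "raw_total_error", "relative_error"),
                   paths$landscape)
  jsonlite::write_json(
    list(reps = land$reps, seed = land$seed,
         normalisation = land$normalisation,
         wf_grid = land$wf_grid, prior_grid_ms = land$prior_grid_ms,
         motor_noise_coef = land$motor_noise_coef,
         trials_per_duration = config$paradigm_design$trials_per_duration),
    paths$meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  points <- NULL
  if (!is.null(groups)) {
    points <- superimpose_groups(land, groups)
    paths$points <- file.path(out_dir, "group_points.json")
    jsonlite::write_json(points, paths$points, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (isTRUE(lb$figure)) {
    paths$figure <- file.path(out_dir, "landscape.png")
    ggplot2::ggsave(paths$figure, autoplot(land, groups = groups),
                    width = 7, height = 5, dpi = 150)
  }
  log_stage("landscape", seed = config$seed,
            cells = nrow(land$grid), reps = land$reps)
  invisible(list(landscape = land, points = points, paths = paths))
}

# internal: accept either a validated run_config or a raw list
ensure_config <- function(config) {
  if (inherits(config, "run_config")) config else validate_run_config(config)
}
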