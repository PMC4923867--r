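# Column contracts for the CSV interchange formats.
trials_schema <- c("session", "trial_index", "stimulus_ms", "reproduced_ms")
participants_schema <- c("participant_id", "group", "true_wf",
                         "true_prior_width_ms", "true_bias_ms")
discrimination_schema <- c("trial_index", "reference_ms", "comparison_ms",
                           "chose_comparison_longer")

# internal: schema check that names every offending column
check_schema <- function(df, schema, what) {
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols) > 0) {
    stop_timeprior("SCHEMA", sprintf(
      "%s is missing required column(s): %s.", what,
      paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

#' Read and write the trial-table CSV formats
#'
#' Readers validate the column contract and report every missing column;
#' extra columns (e.g. `participant_id`, `group`) are preserved. Writers
#' emit plain CSV with the contract columns ordered first.
#'
#' @param path File path.
#' @param trials A reproduction-trial tibble (`session`, `trial_index`,
#'   `stimulus_ms`, `reproduced_ms`, optionally preceded by `participant_id`
#'   and `group`).
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
read_trials_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, trials_schema, basename(path))
  df
}

#' @rdname trial_io
#' @export
write_trials_csv <- function(trials, path) {
  check_schema(trials, trials_schema, "`trials`")
  front <- intersect(c("participant_id", "group", trials_schema), names(trials))
  readr::write_csv(dplyr::relocate(trials, dplyr::all_of(front)), path)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_discrimination_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, discrimination_schema, basename(path))
  df
}

#' Read a pipeline run configuration
#'
#' Configurations are YAML (JSON, a YAML subset, is accepted too) with a
#' top-level `seed`, an optional `paradigm` block (`trials_per_duration`), a
#' `cohorts` list (fields of [cohort_spec()], `label` accepted for
#' `group_label`), an optional `analysis` block (`normaliser_ms`,
#' `match_tolerance_ms`, `split_half`), an optional `landscape` block
#' (`wf_grid`, `prior_grid_ms`, `reps`, `normalisation`) and an
#' `output_dir`.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_timeprior("CONFIG", sprintf("config file '%s' does not exist.", path))
  }
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A raw configuration list (as parsed from YAML/JSON).
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop_timeprior("CONFIG", "config must be a mapping.")
  if (is.null(config$seed)) {
    stop_timeprior("CONFIG", "config field `seed` is required.")
  }
  config$seed <- assert_count(config$seed, "seed", lower = 0L)
  paradigm <- config$paradigm %||% list()
  config$paradigm_design <-
    build_paradigm(trials_per_duration = paradigm$trials_per_duration %||% 7)
  cohorts <- config$cohorts %||% list()
  config$cohort_specs <- purrr::imap(cohorts, function(co, i) {
    co <- as.list(co)
    lab <- co$group_label %||% co$label %||%
      stop_timeprior("CONFIG", sprintf("cohorts[%s]: `label` is required.", i))
    cohort_spec(
      group_label = lab,
      n_participants = co$n_participants %||%
        stop_timeprior("CONFIG",
                       sprintf("cohorts[%s]: `n_participants` is required.", i)),
      wf_mean = co$wf_mean %||%
        stop_timeprior("CONFIG", sprintf("cohorts[%s]: `wf_mean` is required.", i)),
      wf_sd = co$wf_sd %||% 0,
      prior_width_mean_ms = co$prior_width_mean_ms %||% 400,
      prior_width_sd_ms = co$prior_width_sd_ms %||% 0,
      motor_noise_coef = co$motor_noise_coef %||% 0.05,
      bias_mean_ms = co$bias_mean_ms %||% 0,
      bias_sd_ms = co$bias_sd_ms %||% 0,
      seed = co$seed %||% (config$seed + as.integer(i)))
  })
  analysis <- config$analysis %||% list()
  config$analysis <- list(
    normaliser_ms = analysis$normaliser_ms,
    match_tolerance_ms = analysis$match_tolerance_ms %||% 5,
    split_half = analysis$split_half %||% TRUE)
  land <- config$landscape %||% list()
  config$landscape <- list(
    wf_grid = as.numeric(land$wf_grid %||% seq(0.1, 1, by = 0.1)),
    prior_grid_ms = as.numeric(land$prior_grid_ms %||% seq(50, 600, by = 50)),
    reps = land$reps %||% 1000,
    normalisation = land$normalisation %||% "minmax",
    figure = isTRUE(land$figure))
  config$output_dir <- config$output_dir %||% "timeprior-output"
  structure(config, class = "run_config")
}

# internal: one structured log line per pipeline stage
log_stage <- function(stage, ...) {
  fields <- c(list(stage = stage), list(...))
  message(paste0("[timeprior] ",
                 paste(names(fields), unname(fields), sep = "=",
                       collapse = " ")))
}
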