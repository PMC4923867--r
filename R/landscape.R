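#' Model-predicted measures over a (prior width x Weber fraction) grid
#'
#' Monte-Carlo predictions of the regression index and the BIAS/CV error
#' components for every combination of prior width and Weber fraction,
#' averaged across the paradigm's two sessions and over replicates — the
#' simulation set used to draw model curves through group data. The printed
#' settings are prior widths 400/300/200/100 ms crossed with Weber fractions
#' 0 to 1 in steps of 0.1 at 100 repetitions.
#'
#' @param design A [paradigm_design][build_paradigm()].
#' @param prior_widths_ms Prior widths to simulate, ms.
#' @param wf_values Weber fractions to simulate (0 allowed).
#' @param reps Monte-Carlo replicates per cell (default 100).
#' @param seed Integer seed.
#' @param motor_noise_coef Motor-noise coefficient (default 0.05).
#' @return A tibble with columns `prior_width_ms`, `wf`, `regression_index`,
#'   `bias`, `cv`.
#' @examples
#' predict_measures_grid(build_paradigm(), prior_widths_ms = c(200, 400),
#'                       wf_values = c(0.2, 0.4), reps = 20, seed = 1)
#' @export
predict_measures_grid <- function(design, prior_widths_ms = c(100, 200, 300, 400),
                                  wf_values = seq(0, 1, by = 0.1), reps = 100,
                                  seed = 1L, motor_noise_coef = 0.05) {
  if (!inherits(design, "paradigm_design")) {
    stop_timeprior("DOMAIN", "`design` must be a paradigm_design.")
  }
  if (length(prior_widths_ms) < 1L || length(wf_values) < 1L) {
    stop_timeprior("DOMAIN", "both grids must be non-empty.")
  }
  reps <- assert_count(reps, "reps")
  seed <- assert_count(seed, "seed", lower = 0L)
  cells <- tidyr::expand_grid(prior_width_ms = sort(prior_widths_ms),
                              wf = sort(wf_values))
  sessions <- as_session_list(design)
  withr::with_seed(seed, {
    res <- purrr::pmap(cells, function(prior_width_ms, wf) {
      per_sess <- purrr::map(sessions, function(sess) {
        mc_session_measures(prior_width_ms, wf, motor_noise_coef, sess, reps)
      })
      # per-replicate session average, then Monte-Carlo mean
      avg <- purrr::reduce(per_sess, `+`) / length(per_sess)
      tibble(regression_index = mean(avg$regression_index),
             bias = mean(avg$bias), cv = mean(avg$cv))
    })
  })
  dplyr::bind_cols(cells, dplyr::bind_rows(res))
}

#' Monte-Carlo relative-error landscape
#'
#' Simulates the total reproduction error (RMS of the BIAS/CV partition,
#' session-averaged) for every (Weber fraction, prior width) cell, then
#' normalises within each Weber-fraction row so the prior widths that
#' minimise error at a given temporal resolution stand out. The default
#' normalisation is min-max to `[0, 1]`; `"ratio_min"` divides each row by
#' its minimum instead.
#'
#' @param design A [paradigm_design][build_paradigm()].
#' @param wf_grid Weber-fraction grid (values in (0, 1]).
#' @param prior_grid_ms Prior-width grid, ms (at least two values).
#' @param reps Monte-Carlo replicates per cell (default 1000; the printed
#'   landscape used 10,000).
#' @param seed Integer seed.
#' @param normalisation `"minmax"` (default) or `"ratio_min"`.
#' @param motor_noise_coef Motor-noise coefficient (default 0.05).
#' @return An object of class `error_landscape` holding the long-form grid
#'   (`wf`, `prior_width_ms`, `raw_total_error`, `mc_se`, `relative_error`)
#'   plus the settings that produced it. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' relative_error_landscape(build_paradigm(), wf_grid = c(0.2, 0.4),
#'                          prior_grid_ms = c(100, 200, 400), reps = 50,
#'                          seed = 2)
#' @export
relative_error_landscape <- function(design, wf_grid = seq(0.1, 1, by = 0.1),
                                     prior_grid_ms = seq(50, 600, by = 50),
                                     reps = 1000, seed = 1L,
                                     normalisation = c("minmax", "ratio_min"),
                                     motor_noise_coef = 0.05) {
  if (!inherits(design, "paradigm_design")) {
    stop_timeprior("DOMAIN", "`design` must be a paradigm_design.")
  }
  normalisation <- match.arg(normalisation)
  if (length(prior_grid_ms) < 2L) {
    stop_timeprior("DOMAIN", "`prior_grid_ms` needs at least two values.")
  }
  if (any(wf_grid <= 0) || any(wf_grid > 1)) {
    stop_timeprior("DOMAIN", "`wf_grid` values must lie in (0, 1].")
  }
  if (any(prior_grid_ms <= 0)) {
    stop_timeprior("DOMAIN", "`prior_grid_ms` values must be positive.")
  }
  reps <- assert_count(reps, "reps", lower = 2L)
  seed <- assert_count(seed, "seed", lower = 0L)
  wf_grid <- sort(wf_grid)
  prior_grid_ms <- sort(prior_grid_ms)
  cells <- tidyr::expand_grid(wf = wf_grid, prior_width_ms = prior_grid_ms)
  sessions <- as_session_list(design)
  withr::with_seed(seed, {
    res <- purrr::pmap(cells, function(wf, prior_width_ms) {
      per_sess <- purrr::map(sessions, function(sess) {
        mc_session_measures(prior_width_ms, wf, motor_noise_coef, sess, reps)
      })
      tot <- purrr::reduce(purrr::map(per_sess, "total_error"), `+`) /
        length(per_sess)
      tibble(raw_total_error = mean(tot), mc_se = sd(tot) / sqrt(reps))
    })
  })
  grid <- dplyr::bind_cols(cells, dplyr::bind_rows(res)) |>
    dplyr::mutate(relative_error = normalise_row(.data$raw_total_error,
                                                 normalisation),
                  .by = "wf")
  structure(
    list(grid = grid, wf_grid = wf_grid, prior_grid_ms = prior_grid_ms,
         reps = reps, seed = seed, normalisation = normalisation,
         motor_noise_coef = motor_noise_coef, design = design),
    class = "error_landscape")
}

# internal: row-wise normalisation of raw errors
normalise_row <- function(x, normalisation) {
  switch(normalisation,
         minmax = if (diff(range(x)) == 0) rep(0, length(x))
                  else (x - min(x)) / (max(x) - min(x)),
         ratio_min = x / min(x))
}

#' @export
print.error_landscape <- function(x, ...) {
  cat(sprintf("<error_landscape> %d WF x %d prior-width cells, %d reps each (seed %d, %s normalisation)\n",
              length(x$wf_grid), length(x$prior_grid_ms), x$reps, x$seed,
              x$normalisation))
  invisible(x)
}

#' @rdname relative_error_landscape
#' @param x,object An `error_landscape`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.error_landscape <- function(x, ...) {
  x$grid
}

#' @rdname relative_error_landscape
#' @exportS3Method generics::glance
glance.error_landscape <- function(x, ...) {
  tibble(n_wf = length(x$wf_grid), n_prior = length(x$prior_grid_ms),
         reps = x$reps, seed = x$seed, normalisation = x$normalisation,
         motor_noise_coef = x$motor_noise_coef)
}

#' @rdname relative_error_landscape
#' @param groups Optional tibble of group points (see
#'   [superimpose_groups()]) drawn over the surface.
#' @exportS3Method ggplot2::autoplot
autoplot.error_landscape <- function(object, groups = NULL, ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$wf, y = .data$prior_width_ms)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$relative_error)) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "relative\nerror") +
    ggplot2::labs(x = "Weber fraction", y = "prior width (ms)",
                  title = "Relative reproduction-error landscape") +
    ggplot2::theme_minimal()
  if (!is.null(groups)) {
    pts <- superimpose_groups(object, groups)
    p <- p +
      ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$prior_width_ms),
                          colour = "white", shape = 22, size = 3,
                          fill = "grey30") +
      ggplot2::geom_text(data = pts,
                         ggplot2::aes(y = .data$prior_width_ms,
                                      label = .data$label),
                         colour = "white", vjust = -1, size = 3)
  }
  p
}

#' Prior width minimising Monte-Carlo reproduction error
#'
#' Searches the prior width that minimises session-averaged total error at a
#' given Weber fraction: a coarse seeded grid pass followed by a
#' golden-section refinement of the same common-random-number objective
#' (every candidate prior is evaluated on identical noise draws, making the
#' objective smooth in the prior). A flat objective — in particular `wf = 0`,
#' where any prior wider than nothing is equivalent — returns the upper
#' search bound with attribute `flat = TRUE`.
#'
#' @param wf Weber fraction (>= 0).
#' @param design A [paradigm_design][build_paradigm()].
#' @param search_range_ms Lower and upper prior-width bounds, ms.
#' @param reps Monte-Carlo replicates per candidate (default 2000).
#' @param seed Integer seed.
#' @param n_grid Coarse-grid size (default 41).
#' @param motor_noise_coef Motor-noise coefficient (default 0.05).
#' @return The optimal prior width in ms, with attribute `flat`.
#' @examples
#' optimal_prior_width(0.36, build_paradigm(), reps = 200, seed = 3)
#' @export
optimal_prior_width <- function(wf, design, search_range_ms = c(25, 1000),
                                reps = 2000, seed = 1L, n_grid = 41,
                                motor_noise_coef = 0.05) {
  assert_number(wf, "wf", lower = 0)
  if (!inherits(design, "paradigm_design")) {
    stop_timeprior("DOMAIN", "`design` must be a paradigm_design.")
  }
  if (length(search_range_ms) != 2L || any(search_range_ms <= 0) ||
      diff(search_range_ms) <= 0) {
    stop_timeprior("DOMAIN", "`search_range_ms` must be an increasing positive pair.")
  }
  reps <- assert_count(reps, "reps", lower = 2L)
  seed <- assert_count(seed, "seed", lower = 0L)
  n_grid <- assert_count(n_grid, "n_grid", lower = 3L)
  sessions <- as_session_list(design)
  objective <- function(prior) {
    # common random numbers: identical draws for every candidate prior
    withr::with_seed(seed, {
      mean(purrr::map_dbl(sessions, function(sess) {
        mean(mc_session_measures(prior, wf, motor_noise_coef, sess,
                                 reps)$total_error)
      }))
    })
  }
  grid <- seq(search_range_ms[1], search_range_ms[2], length.out = n_grid)
  vals <- purrr::map_dbl(grid, objective)
  if (diff(range(vals)) < 1e-10 * max(mean(vals), 1e-12)) {
    out <- search_range_ms[2]
    attr(out, "flat") <- TRUE
    return(out)
  }
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, n_grid)]
  refine <- optimize(objective, lower = lo, upper = hi,
                     tol = diff(search_range_ms) * 1e-4)
  out <- refine$minimum
  attr(out, "flat") <- FALSE
  out
}

#' Place group data on the error landscape
#'
#' Converts each group's measured regression index and Weber fraction into a
#' prior-width coordinate via the prior-width inversion (using the
#' landscape design's cross-session mean stimulus), then reads the group's
#' relative error off the landscape by bilinear interpolation. Points outside
#' the simulated grid are flagged (`in_grid = FALSE`) and get `NA` rather
#' than an extrapolated error.
#'
#' @param landscape An [error_landscape][relative_error_landscape()].
#' @param groups A data frame with columns `label`, `regression_index`, `wf`.
#' @return A tibble with columns `label`, `wf`, `regression_index`,
#'   `prior_width_ms`, `relative_error`, `in_grid`.
#' @examples
#' land <- relative_error_landscape(build_paradigm(), wf_grid = c(0.2, 0.4),
#'                                  prior_grid_ms = c(100, 300, 500),
#'                                  reps = 50, seed = 2)
#' groups <- tibble::tibble(label = c("autistic", "comparison"),
#'                          regression_index = c(0.61, 0.45),
#'                          wf = c(0.36, 0.22))
#' superimpose_groups(land, groups)
#' @export
superimpose_groups <- function(landscape, groups) {
  if (!inherits(landscape, "error_landscape")) {
    stop_timeprior("DOMAIN", "`landscape` must be an error_landscape.")
  }
  groups <- check_trials(groups, c("label", "regression_index", "wf"))
  if (nrow(groups) == 0) {
    stop_timeprior("DOMAIN", "`groups` must contain at least one row.")
  }
  t_bar <- paradigm_mean_stimulus(landscape$design)
  groups |>
    dplyr::mutate(
      prior_width_ms = purrr::map2_dbl(.data$regression_index, .data$wf,
                                       ~ prior_width_from_regression(.x, .y, t_bar)),
      relative_error = purrr::map2_dbl(.data$wf, .data$prior_width_ms,
                                       ~ interp_landscape(landscape, .x, .y)),
      in_grid = !is.na(.data$relative_error)) |>
    dplyr::select("label", "wf", "regression_index", "prior_width_ms",
                  "relative_error", "in_grid")
}

# internal: bilinear interpolation of the relative-error surface; NA outside
interp_landscape <- function(landscape, wf, prior) {
  xs <- landscape$wf_grid
  ys <- landscape$prior_grid_ms
  if (wf < min(xs) || wf > max(xs) || prior < min(ys) || prior > max(ys)) {
    return(NA_real_)
  }
  z <- matrix(landscape$grid$relative_error[order(landscape$grid$wf,
                                                  landscape$grid$prior_width_ms)],
              nrow = length(xs), ncol = length(ys), byrow = TRUE)
  ix <- max(findInterval(wf, xs, rightmost.closed = TRUE), 1L)
  iy <- max(findInterval(prior, ys, rightmost.closed = TRUE), 1L)
  ix2 <- min(ix + 1L, length(xs))
  iy2 <- min(iy + 1L, length(ys))
  tx <- if (ix2 == ix) 0 else (wf - xs[ix]) / (xs[ix2] - xs[ix])
  ty <- if (iy2 == iy) 0 else (prior - ys[iy]) / (ys[iy2] - ys[iy])
  (1 - tx) * (1 - ty) * z[ix, iy] + tx * (1 - ty) * z[ix2, iy] +
    (1 - tx) * ty * z[ix, iy2] + tx * ty * z[ix2, iy2]
}
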