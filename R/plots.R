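#' Plot reproduced against presented durations
#'
#' Trial-level responses with the per-session OLS fit and the equality line;
#' the shallower the fit relative to equality, the stronger the central
#' tendency.
#'
#' @param trials A reproduction-trial table (a `session` column, when
#'   present, facets the plot).
#' @return A ggplot object.
#' @examples
#' trials <- simulate_reproduction(observer_params(400, 0.36),
#'                                 build_paradigm(), seed = 8)
#' plot_reproduction(trials)
#' @export
plot_reproduction <- function(trials) {
  trials <- check_trials(trials)
  p <- ggplot2::ggplot(trials, ggplot2::aes(x = .data$stimulus_ms,
                                            y = .data$reproduced_ms)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.35, size = 0.9) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.8, colour = "firebrick") +
    ggplot2::labs(x = "presented duration (ms)", y = "reproduced duration (ms)") +
    ggplot2::theme_minimal()
  if ("session" %in% names(trials)) {
    p <- p + ggplot2::facet_wrap(~session)
  }
  p
}

#' Plot model-prediction curves with group data
#'
#' Regression index against Weber fraction: one curve per simulated prior
#' width (from [predict_measures_grid()]) with optional group points laid on
#' top, the comparison used to read off which prior width captures each
#' group.
#'
#' @param grid Output of [predict_measures_grid()].
#' @param groups Optional data frame with `label`, `wf`, `regression_index`.
#' @return A ggplot object.
#' @export
plot_regression_curves <- function(grid, groups = NULL) {
  grid <- check_trials(grid, c("prior_width_ms", "wf", "regression_index"))
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$wf,
                                          y = .data$regression_index,
                                          colour = factor(.data$prior_width_ms),
                                          group = .data$prior_width_ms)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_d(name = "prior width (ms)") +
    ggplot2::labs(x = "Weber fraction", y = "regression index") +
    ggplot2::theme_minimal()
  if (!is.null(groups)) {
    groups <- check_trials(groups, c("label", "wf", "regression_index"))
    p <- p +
      ggplot2::geom_point(data = groups, ggplot2::aes(colour = NULL,
                                                      group = NULL),
                          shape = 15, size = 3) +
      ggplot2::geom_text(data = groups,
                         ggplot2::aes(label = .data$label, colour = NULL,
                                      group = NULL),
                         vjust = -1, size = 3)
  }
  p
}
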