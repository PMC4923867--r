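#' Fit a cumulative-Gaussian psychometric function to 2AFC data
#'
#' Maximum-likelihood fit of `P(chose comparison longer)` as a cumulative
#' Gaussian of the comparison duration, via a probit GLM. The fitted SD is
#' the just-noticeable difference; divided by the reference it gives the
#' Weber fraction. Perfect separation (a noiseless, step-function responder)
#' is detected and reported as Weber fraction 0 with the `separation` flag
#' set rather than as a fit failure.
#'
#' @param trials A data frame with columns `comparison_ms` and
#'   `chose_comparison_longer` (logical or 0/1); a `reference_ms` column is
#'   used when present.
#' @param reference_ms Reference duration, ms; taken from the data when the
#'   column is present.
#' @return An object of class `psychometric_fit` with fields
#'   `weber_fraction`, `sigma_ms`, `pse_ms`, `separation`, `n_trials` and the
#'   underlying `model`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' trials <- generate_discrimination_data(0.36, n_trials = 300, seed = 9)
#' fit_psychometric(trials)
#' @export
fit_psychometric <- function(trials, reference_ms = NULL) {
  trials <- check_trials(trials, c("comparison_ms", "chose_comparison_longer"))
  reference_ms <- reference_ms %||%
    (if ("reference_ms" %in% names(trials)) unique(trials$reference_ms)[1] else 500)
  assert_number(reference_ms, "reference_ms", lower = 0, allow_boundary = FALSE)
  y <- as.logical(trials$chose_comparison_longer)
  x <- trials$comparison_ms
  levels_with_both <- length(unique(x[y])) >= 1 && length(unique(x[!y])) >= 1
  if (length(unique(x)) < 2L || !levels_with_both) {
    stop_timeprior("DOMAIN", paste(
      "the psychometric fit needs at least two distinct comparison levels",
      "with both response types represented."))
  }
  # a step-function responder ("longer" iff above some threshold) separates
  # the classes perfectly; the ML slope diverges, so report sigma = 0 with a
  # flag instead of a fit failure
  separation <- max(x[!y]) < min(x[y])
  fit <- suppressWarnings(glm(y ~ x, family = binomial(link = "probit")))
  if (!fit$converged && !separation) {
    stop_timeprior("FIT", sprintf(
      "probit fit did not converge after %d iterations (deviance %.3g).",
      fit$iter, fit$deviance))
  }
  b <- unname(coef(fit))
  if (!separation && b[2] <= 0) {
    stop_timeprior("FIT",
                   "fitted psychometric slope is non-positive; responses may be reversed.")
  }
  sigma <- if (separation) 0 else 1 / b[2]
  pse <- if (separation) (max(x[!y]) + min(x[y])) / 2 else -b[1] / b[2]
  structure(
    list(weber_fraction = sigma / reference_ms, sigma_ms = sigma,
         pse_ms = pse, reference_ms = reference_ms, separation = separation,
         n_trials = nrow(trials), model = fit),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> WF = %.4g (sigma = %.4g ms over %g ms reference), PSE = %.4g ms, n = %d%s\n",
              x$weber_fraction, x$sigma_ms, x$reference_ms, x$pse_ms,
              x$n_trials, if (x$separation) " [perfect separation]" else ""))
  invisible(x)
}

#' @rdname fit_psychometric
#' @param x,object A `psychometric_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.psychometric_fit <- function(x, ...) {
  tibble(term = c("pse_ms", "sigma_ms", "weber_fraction"),
         estimate = c(x$pse_ms, x$sigma_ms, x$weber_fraction))
}

#' @rdname fit_psychometric
#' @exportS3Method generics::glance
glance.psychometric_fit <- function(x, ...) {
  tibble(n_trials = x$n_trials, reference_ms = x$reference_ms,
         separation = x$separation, converged = x$model$converged,
         deviance = x$model$deviance, df_residual = x$model$df.residual)
}

#' Weber fraction from 2AFC discrimination trials
#'
#' Convenience wrapper around [fit_psychometric()] returning just the Weber
#' fraction (fitted psychometric SD divided by the reference duration).
#'
#' @inheritParams fit_psychometric
#' @return A single number; 0 (with the fit's separation flag) for a
#'   noiseless step-function responder.
#' @examples
#' trials <- generate_discrimination_data(0.22, n_trials = 500, seed = 9)
#' weber_fraction_from_2afc(trials)
#' @export
weber_fraction_from_2afc <- function(trials, reference_ms = NULL) {
  fit_psychometric(trials, reference_ms)$weber_fraction
}

#' @rdname fit_psychometric
#' @exportS3Method ggplot2::autoplot
autoplot.psychometric_fit <- function(object, ...) {
  dat <- tibble(comparison_ms = object$model$model$x,
                chose = as.numeric(object$model$model$y))
  obs <- dat |>
    dplyr::summarise(p = mean(.data$chose), n = dplyr::n(),
                     .by = "comparison_ms")
  grid <- tibble(comparison_ms = seq(min(dat$comparison_ms),
                                     max(dat$comparison_ms), length.out = 200))
  grid$p <- pnorm(as.numeric(predict(object$model,
                                     newdata = data.frame(x = grid$comparison_ms))))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$comparison_ms, y = .data$p)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$reference_ms, linetype = 2) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "comparison duration (ms)",
                  y = "P(comparison judged longer)",
                  title = sprintf("Cumulative-Gaussian fit: WF = %.3f",
                                  object$weber_fraction)) +
    ggplot2::theme_minimal()
}
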