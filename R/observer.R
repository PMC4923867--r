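#' Observer parameters for the Bayesian interval-reproduction model
#'
#' Bundles the parameters of one simulated observer: the width of the
#' Gaussian prior over durations, the Weber fraction governing sensory
#' (likelihood) noise, the motor-noise coefficient applied after Bayesian
#' integration, and an optional constant response offset used to emulate the
#' systematic underestimation often seen in empirical reproduction data.
#'
#' The prior mean defaults to the sentinel `"session-mean"`, in which case it
#' is bound to the mean stimulus duration of whichever session is being
#' simulated — the model's stationarity assumption. Pass a number to pin it.
#'
#' @param prior_width_ms Standard deviation of the Gaussian prior, ms (> 0).
#' @param weber_fraction Weber fraction (>= 0); the likelihood SD is
#'   `weber_fraction * mean_stimulus_ms`.
#' @param motor_noise_coef Motor noise level as a fraction of the produced
#'   interval (>= 0). Default 0.05, i.e. 5%.
#' @param constant_bias_ms Additive response offset in ms (default 0; not part
#'   of the core model).
#' @param prior_mean_ms Either the sentinel string `"session-mean"` (default)
#'   or a positive number in ms.
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(prior_width_ms = 400, weber_fraction = 0.36)
#' @export
observer_params <- function(prior_width_ms, weber_fraction,
                            motor_noise_coef = 0.05, constant_bias_ms = 0,
                            prior_mean_ms = "session-mean") {
  assert_number(prior_width_ms, "prior_width_ms", lower = 0, allow_boundary = FALSE)
  assert_number(weber_fraction, "weber_fraction", lower = 0)
  assert_number(motor_noise_coef, "motor_noise_coef", lower = 0)
  assert_number(constant_bias_ms, "constant_bias_ms")
  if (!identical(prior_mean_ms, "session-mean")) {
    assert_number(prior_mean_ms, "prior_mean_ms", lower = 0, allow_boundary = FALSE)
  }
  structure(
    list(prior_width_ms = prior_width_ms, weber_fraction = weber_fraction,
         motor_noise_coef = motor_noise_coef, constant_bias_ms = constant_bias_ms,
         prior_mean_ms = prior_mean_ms),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf("  prior width   : %g ms (mean: %s)\n", x$prior_width_ms,
              if (identical(x$prior_mean_ms, "session-mean")) "session mean"
              else paste0(x$prior_mean_ms, " ms")))
  cat(sprintf("  Weber fraction: %g\n", x$weber_fraction))
  cat(sprintf("  motor noise   : %g (fraction of produced interval)\n",
              x$motor_noise_coef))
  if (x$constant_bias_ms != 0) {
    cat(sprintf("  constant bias : %g ms\n", x$constant_bias_ms))
  }
  invisible(x)
}

#' Likelihood width from a Weber fraction
#'
#' The sensory measurement of a duration is modelled as Gaussian with a
#' standard deviation proportional to the mean stimulus of the session:
#' `sigma_L = WF * t_bar`.
#'
#' @param weber_fraction Weber fraction (>= 0).
#' @param mean_stimulus_ms Mean stimulus duration of the session, ms (> 0).
#' @return Likelihood standard deviation in ms.
#' @examples
#' likelihood_sd(0.36, 1403) # 505.08
#' @export
likelihood_sd <- function(weber_fraction, mean_stimulus_ms) {
  assert_number(weber_fraction, "weber_fraction", lower = 0)
  assert_number(mean_stimulus_ms, "mean_stimulus_ms", lower = 0,
                allow_boundary = FALSE)
  weber_fraction * mean_stimulus_ms
}

#' Posterior mean of the Gaussian observer
#'
#' Conjugate Gaussian update: the reproduced duration is centred on
#' `(mu_P * sigma_L^2 + t * sigma_P^2) / (sigma_P^2 + sigma_L^2)`, a
#' precision-weighted average of the noisy measurement `t` and the prior mean.
#' It always lies between the two.
#'
#' @param measurement_ms Noisy sensory measurement, ms.
#' @param prior_mean_ms Prior mean, ms.
#' @param prior_sd_ms Prior SD, ms (> 0).
#' @param likelihood_sd_ms Likelihood SD, ms (>= 0).
#' @return Posterior mean in ms.
#' @examples
#' posterior_mean(1536, 1271, 400, 457.6)
#' @export
posterior_mean <- function(measurement_ms, prior_mean_ms, prior_sd_ms,
                           likelihood_sd_ms) {
  if (!is.numeric(prior_sd_ms) || any(!is.finite(prior_sd_ms)) ||
      any(prior_sd_ms <= 0)) {
    stop_timeprior("DOMAIN", "`prior_sd_ms` must be positive and finite.")
  }
  if (any(!is.finite(likelihood_sd_ms)) || any(likelihood_sd_ms < 0)) {
    stop_timeprior("DOMAIN", "`likelihood_sd_ms` must be non-negative and finite.")
  }
  w <- prior_sd_ms^2 / (prior_sd_ms^2 + likelihood_sd_ms^2)
  prior_mean_ms + w * (measurement_ms - prior_mean_ms)
}

#' Posterior width of the Gaussian observer
#'
#' `sigma_R = sigma_P * sigma_L / sqrt(sigma_P^2 + sigma_L^2)`, never larger
#' than either component width.
#'
#' @inheritParams posterior_mean
#' @return Posterior standard deviation in ms.
#' @examples
#' posterior_sd(400, 505.08)
#' @export
posterior_sd <- function(prior_sd_ms, likelihood_sd_ms) {
  if (!is.numeric(prior_sd_ms) || any(!is.finite(prior_sd_ms)) ||
      any(prior_sd_ms <= 0)) {
    stop_timeprior("DOMAIN", "`prior_sd_ms` must be positive and finite.")
  }
  if (any(!is.finite(likelihood_sd_ms)) || any(likelihood_sd_ms < 0)) {
    stop_timeprior("DOMAIN", "`likelihood_sd_ms` must be non-negative and finite.")
  }
  prior_sd_ms * likelihood_sd_ms / sqrt(prior_sd_ms^2 + likelihood_sd_ms^2)
}

#' Model-predicted slope of the reproduction line
#'
#' For the Gaussian observer, the expected slope of reproduced against
#' presented duration is `sigma_P^2 / (sigma_P^2 + sigma_L^2)`: 1 when the
#' likelihood is noiseless (veridical reproduction), 0 when temporal
#' resolution is arbitrarily poor (complete regression to the mean).
#'
#' @inheritParams posterior_sd
#' @return Slope in `[0, 1]`.
#' @examples
#' predicted_slope(400, 505.08)
#' 1 - predicted_slope(400, likelihood_sd(0.36, 1271)) # regression index, short
#' @export
predicted_slope <- function(prior_sd_ms, likelihood_sd_ms) {
  if (!is.numeric(prior_sd_ms) || any(!is.finite(prior_sd_ms)) ||
      any(prior_sd_ms <= 0)) {
    stop_timeprior("DOMAIN", "`prior_sd_ms` must be positive and finite.")
  }
  if (any(likelihood_sd_ms < 0)) {
    stop_timeprior("DOMAIN", "`likelihood_sd_ms` must be non-negative.")
  }
  # written to stay finite as likelihood_sd_ms -> Inf
  1 / (1 + (likelihood_sd_ms / prior_sd_ms)^2)
}

#' Prior width from a regression index and a Weber fraction
#'
#' Inverts the predicted-slope relation: writing the regression index as
#' `r = 1 - slope`, the prior width solving it is
#' `sigma_P = sigma_L * sqrt((1 - r) / r)` with `sigma_L = WF * t_bar`.
#' This is how group prior widths are placed on the error landscape from the
#' measured regression index and Weber fraction.
#'
#' @param regression_index Regression index in (0, 1); the open interval is
#'   required — zero or complete regression has no finite inverse.
#' @param weber_fraction Weber fraction (> 0).
#' @param mean_stimulus_ms Mean stimulus duration, ms (> 0).
#' @return Prior standard deviation in ms.
#' @examples
#' prior_width_from_regression(0.61, 0.36, 1403) # ~404 ms
#' @export
prior_width_from_regression <- function(regression_index, weber_fraction,
                                        mean_stimulus_ms) {
  assert_number(regression_index, "regression_index", lower = 0, upper = 1,
                allow_boundary = FALSE)
  assert_number(weber_fraction, "weber_fraction", lower = 0,
                allow_boundary = FALSE)
  sig_l <- likelihood_sd(weber_fraction, mean_stimulus_ms)
  sig_l * sqrt((1 - regression_index) / regression_index)
}
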