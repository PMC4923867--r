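#' Simulate one observer completing a reproduction session
#'
#' Trial-level generative model of the Bayesian observer. For each trial the
#' sensory measurement is drawn as `Normal(S_i, sigma_L)` with
#' `sigma_L = WF * t_bar`; the response is the posterior mean of that
#' measurement under the Gaussian prior, plus zero-mean Gaussian motor noise
#' at `motor_noise_coef` times the produced interval, plus any constant bias.
#' Presentation order is randomised within the session. Responses below 1 ms
#' are clamped to 1 ms with a warning.
#'
#' @param params An [observer_params()] object.
#' @param design A [session_design()] (one session) or a
#'   [paradigm_design][build_paradigm()] (both sessions are simulated).
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @param motor_noise_on Where the motor-noise SD is anchored:
#'   `"posterior"` (default; 5% of the trial's noise-free posterior mean) or
#'   `"stimulus"` (5% of the presented duration).
#' @return A tibble with columns `session`, `trial_index`, `stimulus_ms`,
#'   `reproduced_ms`.
#' @examples
#' params <- observer_params(prior_width_ms = 400, weber_fraction = 0.36)
#' simulate_reproduction(params, build_paradigm(), seed = 1)
#' @export
simulate_reproduction <- function(params, design, seed,
                                  motor_noise_on = c("posterior", "stimulus")) {
  if (!inherits(params, "observer_params")) {
    stop_timeprior("DOMAIN", "`params` must be an observer_params object.")
  }
  motor_noise_on <- match.arg(motor_noise_on)
  seed <- assert_count(seed, "seed", lower = 0L)
  sessions <- as_session_list(design)
  withr::with_seed(seed, {
    out <- purrr::map(sessions, function(sess) {
      simulate_one_session(params, sess, motor_noise_on)
    })
  })
  dplyr::bind_rows(out)
}

# internal: one session under the current RNG state
simulate_one_session <- function(params, sess, motor_noise_on) {
  n <- length(sess$durations_ms) * sess$trials_per_duration
  stimulus <- sample(rep(sess$durations_ms, each = sess$trials_per_duration))
  mu_p <- if (identical(params$prior_mean_ms, "session-mean")) {
    sess$mean_stimulus_ms
  } else {
    params$prior_mean_ms
  }
  sig_l <- likelihood_sd(params$weber_fraction, sess$mean_stimulus_ms)
  measurement <- rnorm(n, mean = stimulus, sd = sig_l)
  post <- posterior_mean(measurement, mu_p, params$prior_width_ms, sig_l)
  motor_sd <- params$motor_noise_coef *
    switch(motor_noise_on, posterior = abs(post), stimulus = stimulus)
  response <- post + rnorm(n, 0, 1) * motor_sd + params$constant_bias_ms
  if (any(response < 1)) {
    warn(sprintf("%d response(s) below 1 ms clamped to the 1 ms floor.",
                 sum(response < 1)))
    response <- pmax(response, 1)
  }
  tibble(session = sess$label, trial_index = seq_len(n),
         stimulus_ms = stimulus, reproduced_ms = response)
}

# internal vectorised Monte-Carlo core: `reps` independent sessions at one
# (prior width, WF) setting, returning per-replicate summary measures.
# Matrix layout is trials x reps; per-stimulus moments come from rowsum().
mc_session_measures <- function(prior_width_ms, wf, motor_noise_coef, sess,
                                reps, normaliser_ms = sess$mean_stimulus_ms) {
  d <- rep(sess$durations_ms, each = sess$trials_per_duration)
  n <- length(d)
  k <- sess$trials_per_duration
  m <- sess$mean_stimulus_ms
  sig_l <- wf * m
  w <- if (sig_l == 0) 1 else prior_width_ms^2 / (prior_width_ms^2 + sig_l^2)
  meas <- matrix(rnorm(n * reps, mean = d, sd = sig_l), nrow = n)
  post <- m + w * (meas - m)
  resp <- post + matrix(rnorm(n * reps), nrow = n) * (motor_noise_coef * abs(post))
  resp[resp < 1] <- 1
  dc <- d - mean(d)
  slope <- colSums(dc * resp) / sum(dc^2)
  grp_mean <- rowsum(resp, group = d) / k                    # stimuli x reps
  grp_var <- (rowsum(resp^2, group = d) - k * grp_mean^2) / (k - 1)
  bias <- sqrt(colMeans((grp_mean - sess$durations_ms)^2)) / normaliser_ms
  cv <- sqrt(colMeans(grp_var)) / normaliser_ms
  tibble(regression_index = 1 - slope, bias = bias, cv = cv,
         total_error = sqrt(bias^2 + cv^2))
}
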