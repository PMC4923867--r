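# Shared fixtures: all synthetic, built in code at test time.

default_paradigm <- build_paradigm()

# analytic per-session slopes and cross-session regression index for the
# canonical observer (prior 400 ms, WF 0.36) on the default paradigm
analytic_slope <- function(prior, wf, sess) {
  predicted_slope(prior, likelihood_sd(wf, sess$mean_stimulus_ms))
}

analytic_r_avg <- function(prior, wf, paradigm = default_paradigm) {
  1 - mean(c(analytic_slope(prior, wf, paradigm$short),
             analytic_slope(prior, wf, paradigm$long)))
}

# approximate standard error of an OLS slope for a simulated session
slope_se <- function(prior, wf, sess, motor = 0.05) {
  sig_l <- likelihood_sd(wf, sess$mean_stimulus_ms)
  w <- prior^2 / (prior^2 + sig_l^2)
  resid_sd <- sqrt(w^2 * sig_l^2 + (motor * sess$mean_stimulus_ms)^2)
  n <- length(sess$durations_ms) * sess$trials_per_duration
  stim_sd <- sqrt(mean((sess$durations_ms - mean(sess$durations_ms))^2))
  resid_sd / (stim_sd * sqrt(n))
}

# exact trial table with a prescribed slope/intercept (no noise)
linear_trials <- function(slope, intercept, durations = seq(1000, 1500, 50),
                          k = 3, session = "short") {
  stimulus <- rep(durations, each = k)
  tibble::tibble(session = session, trial_index = seq_along(stimulus),
                 stimulus_ms = stimulus,
                 reproduced_ms = intercept + slope * stimulus)
}

# closed-form optimal prior width for one session's Monte-Carlo objective
# (finite trials-per-duration k inflate the bias term by Var/k)
analytic_optimal_prior <- function(wf, sess, motor = 0.05) {
  k <- sess$trials_per_duration
  sig_l <- likelihood_sd(wf, sess$mean_stimulus_ms)
  sig_s2 <- mean((sess$durations_ms - mean(sess$durations_ms))^2)
  num <- sig_s2 * sig_l^2
  den <- (1 + 1 / k) * ((1 + motor^2) * sig_l^2 + motor^2 * sig_s2)
  sqrt(num / den)
}
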