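test_that("the reproduction line is fit by ordinary least squares", {
  toy <- tibble::tibble(stimulus_ms = c(1000, 1200, 1400),
                        reproduced_ms = c(1100, 1200, 1300))
  fit <- fit_reproduction_line(toy)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept_ms, 600)
  veridical <- linear_trials(1, 0)
  expect_equal(fit_reproduction_line(veridical)$slope, 1)
  expect_equal(fit_reproduction_line(veridical)$intercept_ms, 0)
  flat <- linear_trials(0, 1250)
  expect_equal(fit_reproduction_line(flat)$slope, 0)
  expect_equal(fit_reproduction_line(flat)$intercept_ms, 1250)
  one_level <- tibble::tibble(stimulus_ms = rep(1000, 5),
                              reproduced_ms = rnorm(5, 1000, 10))
  expect_error(fit_reproduction_line(one_level), class = "timeprior_error")
  expect_error(fit_reproduction_line(dplyr::select(toy, -reproduced_ms)),
               class = "timeprior_error")
})

test_that("regression index is one minus the slope and offset-invariant", {
  expect_equal(regression_index(linear_trials(1, 0)), 0)
  expect_equal(regression_index(linear_trials(0.39, 500)), 0.61)
  set.seed(55)
  noisy <- linear_trials(0.7, 200)
  noisy$reproduced_ms <- noisy$reproduced_ms + rnorm(nrow(noisy), 0, 40)
  shifted <- dplyr::mutate(noisy, reproduced_ms = reproduced_ms - 120)
  expect_equal(regression_index(noisy), regression_index(shifted))
})

test_that("regression index of a large simulated session matches the analytic value", {
  sess <- session_design("short", seq(1006, 1536, length.out = 11), 100)
  tr <- simulate_reproduction(observer_params(400, 0.36), sess, seed = 61)
  pred <- 1 - analytic_slope(400, 0.36, sess)
  expect_equal(regression_index(tr), pred,
               tolerance = 4 * slope_se(400, 0.36, sess) / pred)
})

test_that("error partition: trivial cases and the quadratic identity", {
  clean <- linear_trials(1, 0, k = 3)
  ec <- error_components(clean, normaliser_ms = 1250)
  expect_equal(unlist(ec), c(bias = 0, cv = 0, total_error = 0))
  offset <- linear_trials(1, 125, k = 3)
  ec2 <- error_components(offset, normaliser_ms = 1250)
  expect_equal(ec2$bias, 0.1)
  expect_equal(ec2$cv, 0)
  expect_equal(ec2$total_error, 0.1)
  set.seed(77)
  for (i in 1:20) {
    tr <- linear_trials(stats::runif(1, 0, 1.2), stats::runif(1, -100, 400),
                        k = 5)
    tr$reproduced_ms <- tr$reproduced_ms + rnorm(nrow(tr), 0, 60)
    ec3 <- error_components(tr)
    expect_equal(ec3$total_error^2, ec3$bias^2 + ec3$cv^2, tolerance = 1e-12)
  }
  expect_error(error_components(clean, normaliser_ms = 0),
               class = "timeprior_error")
  single <- tibble::tibble(stimulus_ms = c(1000, 1100), reproduced_ms = c(1, 2))
  expect_error(error_components(single), class = "timeprior_error")
})

test_that("a smaller normaliser inflates both error components", {
  set.seed(78)
  tr <- linear_trials(0.8, 100, k = 5)
  tr$reproduced_ms <- tr$reproduced_ms + rnorm(nrow(tr), 0, 50)
  big <- error_components(tr, normaliser_ms = 1250)
  small <- error_components(tr, normaliser_ms = 625)
  expect_equal(small$bias, 2 * big$bias)
  expect_equal(small$cv, 2 * big$cv)
})

test_that("psychometric fit flags perfect separation as a zero Weber fraction", {
  d <- generate_discrimination_data(1e-9, placement_wf = 0.3, n_trials = 100,
                                    n_levels = 8, seed = 81)
  fit <- fit_psychometric(d)
  expect_true(fit$separation)
  expect_equal(fit$weber_fraction, 0)
  expect_equal(weber_fraction_from_2afc(d), 0)
  expect_error(fit_psychometric(dplyr::filter(d, comparison_ms > 500)),
               class = "timeprior_error")
})

test_that("tidy and glance summarise a psychometric fit", {
  d <- generate_discrimination_data(0.3, n_trials = 400, seed = 83)
  fit <- fit_psychometric(d)
  td <- tidy(fit)
  expect_equal(td$term, c("pse_ms", "sigma_ms", "weber_fraction"))
  expect_equal(td$estimate[3], fit$weber_fraction)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_false(gl$separation)
  expect_equal(gl$n_trials, 400)
})

test_that("context dependency: trivial constructions and the Bayesian oracle", {
  short <- linear_trials(1, 0, durations = seq(1006, 1536, 53), k = 2,
                         session = "short")
  long_same <- dplyr::mutate(linear_trials(1, 0, durations = seq(1270, 1800, 53),
                                           k = 2, session = "long"))
  # identical responses on the (1 ms offset) common stimuli -> ~stimulus gap only
  expect_equal(context_dependency(short, long_same), -1)
  long_up <- dplyr::mutate(long_same, reproduced_ms = reproduced_ms + 50)
  expect_equal(context_dependency(short, long_up), 49)
  expect_error(context_dependency(short, long_same, match_tolerance_ms = 0.5),
               class = "timeprior_error")

  # Bayesian observer with session-mean priors: mean difference on common
  # stimuli predicted from the two sessions' posterior-mean lines
  par <- build_paradigm(trials_per_duration = 400)
  p <- observer_params(400, 0.36)
  tr <- simulate_reproduction(p, par, seed = 85)
  got <- context_dependency(dplyr::filter(tr, session == "short"),
                            dplyr::filter(tr, session == "long"))
  w_s <- analytic_slope(400, 0.36, par$short)
  w_l <- analytic_slope(400, 0.36, par$long)
  common_s <- par$short$durations_ms[par$short$durations_ms >= 1270]
  common_l <- par$long$durations_ms[par$long$durations_ms <= 1537]
  pred <- mean((1535 + w_l * (common_l - 1535)) - (1271 + w_s * (common_s - 1271)))
  expect_gt(got, 0)
  expect_equal(got, pred, tolerance = 15 / pred)
})

test_that("split-half regression indices behave on constructed and stationary data", {
  ver <- linear_trials(1, 0, k = 4)
  expect_equal(split_half_regression(ver)$regression_index, c(0, 0))
  # slope 1 in the first half, slope 0.5 in the second
  first <- linear_trials(1, 0, k = 2)
  second <- linear_trials(0.5, 600, k = 2)
  second$trial_index <- second$trial_index + nrow(first)
  piecewise <- dplyr::bind_rows(first, second)
  expect_equal(split_half_regression(piecewise)$regression_index, c(0, 0.5))
  # stationary observer: halves agree up to Monte-Carlo noise
  sess <- session_design("short", seq(1006, 1536, length.out = 11), 400)
  tr <- simulate_reproduction(observer_params(400, 0.36), sess, seed = 87)
  sh <- split_half_regression(tr)
  half_se <- slope_se(400, 0.36, sess) * sqrt(2)
  expect_lt(abs(diff(sh$regression_index)), 5 * sqrt(2) * half_se)
  expect_error(split_half_regression(ver[1:3, ]), class = "timeprior_error")
})

test_that("Cohen's d reproduces the printed group comparison", {
  expect_equal(cohens_d(0.36, 0.21, 23, 0.22, 0.13, 23), 0.80, tolerance = 0.005)
  expect_equal(cohens_d(0.5, 0.2, 10, 0.5, 0.3, 10), 0)
  expect_equal(cohens_d(1, 1, 8, 0, 1, 8), 1)
  expect_error(cohens_d(1, 0, 8, 0, 0, 8), class = "timeprior_error")
  expect_error(cohens_d(1, 1, 1, 0, 1, 8), class = "timeprior_error")
})

test_that("session_measures groups by participant and session", {
  spec <- cohort_spec("g", 2, wf_mean = 0.3, seed = 91)
  cohort <- generate_cohort(spec)
  m <- session_measures(cohort$trials)
  expect_equal(nrow(m), 4)
  expect_setequal(names(m), c("participant_id", "group", "session", "slope",
                              "intercept_ms", "regression_index", "bias",
                              "cv", "total_error"))
  expect_equal(m$regression_index, 1 - m$slope)
  expect_equal(m$total_error^2, m$bias^2 + m$cv^2, tolerance = 1e-12)
})
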