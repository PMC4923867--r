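test_that("the prediction grid reproduces the analytic regression indices", {
  grid <- predict_measures_grid(default_paradigm,
                                prior_widths_ms = c(200, 400),
                                wf_values = c(0, 0.36, 0.7),
                                reps = 200, seed = 101)
  expect_equal(nrow(grid), 6)
  # veridical limit: WF = 0 gives ~0 regression at every prior
  expect_true(all(abs(grid$regression_index[grid$wf == 0]) < 0.01))
  # canonical cell: prior 400 ms, WF 0.36 -> session-averaged r ~ 0.61
  cell <- grid[grid$prior_width_ms == 400 & grid$wf == 0.36, ]
  expect_equal(cell$regression_index, analytic_r_avg(400, 0.36),
               tolerance = 0.02 / 0.61)
  # monotone in WF at fixed prior (inherited from the slope formula)
  for (pw in c(200, 400)) {
    r_col <- grid$regression_index[grid$prior_width_ms == pw]
    expect_true(all(diff(r_col) > 0))
  }
})

test_that("the relative-error landscape is normalised per Weber-fraction row", {
  land <- relative_error_landscape(default_paradigm,
                                   wf_grid = c(0.2, 0.5, 0.8),
                                   prior_grid_ms = c(100, 200, 300, 400),
                                   reps = 300, seed = 103)
  g <- tidy(land)
  expect_true(all(g$raw_total_error >= 0))
  rows <- split(g$relative_error, g$wf)
  for (r in rows) {
    expect_equal(min(r), 0)
    expect_equal(max(r), 1)
  }
  expect_true(all(g$relative_error >= 0 & g$relative_error <= 1))
  # deterministic under a fixed seed
  land2 <- relative_error_landscape(default_paradigm,
                                    wf_grid = c(0.2, 0.5, 0.8),
                                    prior_grid_ms = c(100, 200, 300, 400),
                                    reps = 300, seed = 103)
  expect_identical(tidy(land), tidy(land2))
  # ratio-to-minimum variant bottoms out at 1
  land3 <- relative_error_landscape(default_paradigm, wf_grid = c(0.2, 0.5),
                                    prior_grid_ms = c(100, 300),
                                    reps = 100, seed = 104,
                                    normalisation = "ratio_min")
  g3 <- tidy(land3)
  expect_equal(min(g3$relative_error[g3$wf == 0.2]), 1)
  expect_error(relative_error_landscape(default_paradigm, wf_grid = 0.3,
                                        prior_grid_ms = 300, reps = 100),
               class = "timeprior_error")
  expect_error(relative_error_landscape(default_paradigm, wf_grid = 1.4,
                                        prior_grid_ms = c(100, 300), reps = 100),
               class = "timeprior_error")
  expect_error(relative_error_landscape(default_paradigm, wf_grid = 0.3,
                                        prior_grid_ms = c(100, 300), reps = 1),
               class = "timeprior_error")
})

test_that("raw landscape cells are stable when replicates double", {
  args <- list(design = default_paradigm, wf_grid = c(0.2, 0.5, 0.8),
               prior_grid_ms = c(100, 200, 300, 400))
  a <- do.call(relative_error_landscape, c(args, list(reps = 1000, seed = 105)))
  b <- do.call(relative_error_landscape, c(args, list(reps = 2000, seed = 106)))
  ga <- tidy(a)
  gb <- tidy(b)
  mc_bound <- 3 * sqrt(ga$mc_se^2 + gb$mc_se^2)
  expect_true(all(abs(ga$raw_total_error - gb$raw_total_error) <= mc_bound))
})

test_that("optimal prior width matches brute force and the closed form", {
  wf <- 0.4
  opt <- optimal_prior_width(wf, default_paradigm, search_range_ms = c(50, 600),
                             reps = 800, seed = 107)
  expect_false(attr(opt, "flat"))
  # brute-force grid search through the trial-level simulator and the
  # estimator path (independent of the vectorised Monte-Carlo core)
  brute_grid <- seq(50, 600, by = 50)
  brute <- vapply(seq_along(brute_grid), function(j) {
    pw <- brute_grid[j]
    mean(vapply(1:150, function(i) {
      sess <- if (i %% 2 == 0) default_paradigm$short else default_paradigm$long
      tr <- simulate_reproduction(observer_params(pw, wf), sess,
                                  seed = 7000 + 1000 * j + i)
      error_components(tr)$total_error
    }, numeric(1)))
  }, numeric(1))
  expect_lte(abs(brute_grid[which.min(brute)] - opt), 50)
  # closed-form optimum for the finite-trial objective (per session)
  cf <- mean(c(analytic_optimal_prior(wf, default_paradigm$short),
               analytic_optimal_prior(wf, default_paradigm$long)))
  expect_equal(as.numeric(opt), cf, tolerance = 0.15)
})

test_that("optimal prior search flags a flat objective at zero Weber fraction", {
  opt <- optimal_prior_width(0, default_paradigm, search_range_ms = c(50, 500),
                             reps = 50, seed = 109, n_grid = 5)
  expect_true(attr(opt, "flat"))
  expect_equal(as.numeric(opt), 500)
})

test_that("landscape row argmin agrees with the optimal-prior search", {
  land <- relative_error_landscape(default_paradigm, wf_grid = c(0.4, 0.8),
                                   prior_grid_ms = seq(50, 450, by = 50),
                                   reps = 1500, seed = 111)
  g <- tidy(land)
  for (wf in c(0.4, 0.8)) {
    row <- g[g$wf == wf, ]
    argmin <- row$prior_width_ms[which.min(row$raw_total_error)]
    opt <- optimal_prior_width(wf, default_paradigm,
                               search_range_ms = c(50, 450), reps = 1500,
                               seed = 112)
    expect_lte(abs(argmin - opt), 50)
  }
})

test_that("group data are placed on the landscape via the prior-width inversion", {
  land <- relative_error_landscape(default_paradigm,
                                   wf_grid = seq(0.1, 0.6, by = 0.1),
                                   prior_grid_ms = seq(100, 500, by = 100),
                                   reps = 400, seed = 113)
  groups <- tibble::tibble(label = c("autistic", "comparison", "outside"),
                           regression_index = c(0.61, 0.45, 0.9),
                           wf = c(0.36, 0.22, 0.05))
  pts <- superimpose_groups(land, groups)
  expect_equal(pts$prior_width_ms[1], 403.8569, tolerance = 1e-6)
  expect_equal(pts$prior_width_ms[2], 341.2365, tolerance = 1e-6)
  expect_true(all(pts$in_grid[1:2]))
  # the third point's inverted prior (~23 ms) falls below the grid
  expect_false(pts$in_grid[3])
  expect_true(is.na(pts$relative_error[3]))
  # a point sitting at a row's raw-error argmin has ~0 relative error
  row <- dplyr::filter(tidy(land), wf == 0.4)
  best_prior <- row$prior_width_ms[which.min(row$raw_total_error)]
  r_at_best <- 1 - predicted_slope(best_prior, likelihood_sd(0.4, 1403))
  at_min <- superimpose_groups(
    land, tibble::tibble(label = "opt", regression_index = r_at_best, wf = 0.4))
  expect_lt(at_min$relative_error, 0.15)
  # the measured autistic-like point sits in a worse region than the
  # ability-matched optimum at the same Weber fraction
  opt_r <- 1 - predicted_slope(best_prior, likelihood_sd(0.36, 1403))
  both <- superimpose_groups(
    land, tibble::tibble(label = c("measured", "optimal"),
                         regression_index = c(0.61, opt_r), wf = 0.36))
  expect_gt(both$relative_error[1], both$relative_error[2])
})

test_that("the autistic-like group point lies in a higher relative-error region than the matched optimum", {
  land <- relative_error_landscape(default_paradigm,
                                   wf_grid = c(0.3, 0.36, 0.4),
                                   prior_grid_ms = seq(100, 450, by = 50),
                                   reps = 500, seed = 115)
  opt <- optimal_prior_width(0.36, default_paradigm,
                             search_range_ms = c(100, 450), reps = 500,
                             seed = 116)
  r_opt <- 1 - predicted_slope(as.numeric(opt), likelihood_sd(0.36, 1403))
  pts <- superimpose_groups(
    land, tibble::tibble(label = c("autistic", "matched-optimum"),
                         regression_index = c(0.61, r_opt), wf = c(0.36, 0.36)))
  expect_gt(pts$relative_error[1], pts$relative_error[2])
})
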