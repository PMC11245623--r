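test_that("the reference condition means reproduce the published fit", {
  curve <- table2_curve()
  expect_identical(curve$n_obs, 16L)
  expect_equal(curve$a, -0.28, tolerance = 0.02)
  expect_equal(curve$b, 1.44, tolerance = 0.02)
  expect_lt(curve$a, 0)
})

test_that("noiseless quadratic data are recovered exactly", {
  temps <- c(200, 225, 250, 300, 325, 350)
  x <- (temps - 200) / 150
  obs <- data.frame(temperature_C = temps, duration_h = 2,
                    mean_lw_ratio = 1.5 - 0.3 * x^2)
  fit <- fit_curve(obs)
  expect_equal(fit$a, -0.3, tolerance = 1e-9)
  expect_equal(fit$b, 1.5, tolerance = 1e-9)
  expect_lt(fit$fit_residual, 1e-18)
})

test_that("the least-squares estimator is unbiased under noise", {
  # Monte-Carlo oracle: many replicate fits at known truth
  temps <- rep(c(200, 250, 300, 350), each = 4)
  x <- (temps - 200) / 150
  set.seed(42)
  coefs <- t(replicate(200, {
    obs <- data.frame(temperature_C = temps, duration_h = 2,
                      mean_lw_ratio = 1.44 - 0.28 * x^2 +
                        rnorm(length(x), sd = 0.05))
    f <- fit_curve(obs)
    c(f$a, f$b)
  }))
  se <- apply(coefs, 2, sd) / sqrt(nrow(coefs))
  expect_lt(abs(mean(coefs[, 1]) - (-0.28)), 2 * se[1])
  expect_lt(abs(mean(coefs[, 2]) - 1.44), 2 * se[2])
})

test_that("degenerate fit inputs are rejected", {
  expect_error(fit_curve(data.frame(temperature_C = c(250, 250, 250),
                                    duration_h = 2,
                                    mean_lw_ratio = c(1.4, 1.38, 1.42))),
               class = "carposort_rank_error")
  expect_error(fit_curve(data.frame(temperature_C = 250, duration_h = 2,
                                    mean_lw_ratio = 1.4)),
               class = "carposort_parameter_error")
})

test_that("temperature estimation inverts the forward model", {
  curve <- structure(list(a = -0.28, b = 1.44, t_zero = 200, t_one = 350,
                          fit_residual = 0, n_obs = 16L),
                     class = "charring_curve")
  expect_identical(estimate_temperature(1.44, curve)$temperature_hat, 200)
  # forward value at x = 1 inverts back to 350 degrees C
  expect_equal(estimate_temperature(1.16, curve)$temperature_hat, 350,
               tolerance = 1e-9)
  # ratios near 1 extrapolate beyond the calibrated range
  expect_equal(estimate_temperature(1.00, curve)$temperature_hat,
               200 + 150 * sqrt(0.44 / 0.28), tolerance = 1e-9)
  # exact inverse on a grid
  for (r in seq(1.0, 1.44, by = 0.04)) {
    est <- estimate_temperature(r, curve)
    expect_lt(abs(predict_ratio(curve, est$temperature_hat) - r), 1e-12)
  }
  # monotone: lower ratio, higher temperature
  t_hat <- estimate_temperature(seq(1.44, 1.0, by = -0.02),
                                curve)$temperature_hat
  expect_true(all(diff(t_hat) > 0))
  expect_error(estimate_temperature(NaN, curve),
               class = "carposort_parameter_error")
})

test_that("ratios above the intercept clamp to the mild end", {
  curve <- table2_curve()
  est <- estimate_temperature(c(1.5, 2.0), curve)
  expect_true(all(est$clamped))
  expect_identical(est$temperature_hat, c(200, 200))
})

test_that("refitting curve-generated means is a fixed point", {
  curve <- table2_curve()
  temps <- rep(c(200, 250, 300, 350), 2)
  obs <- data.frame(temperature_C = temps,
                    duration_h = rep(c(2, 8), each = 4),
                    mean_lw_ratio = predict_ratio(curve, temps))
  refit <- fit_curve(obs)
  expect_equal(refit$a, curve$a, tolerance = 1e-9)
  expect_equal(refit$b, curve$b, tolerance = 1e-9)
})

test_that("sorting applies the acceptance threshold with its boundary", {
  curve <- structure(list(a = -0.28, b = 1.44, t_zero = 200, t_one = 350,
                          fit_residual = 0, n_obs = 16L),
                     class = "charring_curve")
  boundary_ratio <- predict_ratio(curve, 275)     # exactly 275 degrees C
  s <- sort_seeds(data.frame(lw_ratio = c(1.44, boundary_ratio, 1.16)),
                  curve, threshold_C = 275)
  expect_identical(s$decisions$accepted, c(TRUE, TRUE, FALSE))
  expect_identical(s$decisions$reason,
                   c("in-range", "in-range", "above-threshold"))
  # acceptance is monotone in the ratio
  ratios <- seq(1.0, 1.6, by = 0.01)
  dec <- sort_seeds(data.frame(lw_ratio = ratios), curve)$decisions
  expect_true(all(diff(dec$accepted) >= 0))
})

test_that("ratios above the intercept are accepted as mild charring", {
  curve <- table2_curve()
  s <- sort_seeds(data.frame(lw_ratio = c(1.50, 1.60)), curve)
  expect_true(all(s$decisions$accepted))
  expect_true(all(s$decisions$reason == "ratio-above-intercept-clamped"))
})

test_that("empty sorting input gives an empty summary, not an error", {
  s <- sort_seeds(data.frame(lw_ratio = numeric(0)), table2_curve())
  expect_identical(nrow(s$decisions), 0L)
  expect_identical(nrow(s$summary), 0L)
})

test_that("per-group sorting summaries count acceptances", {
  curve <- table2_curve()
  tab <- data.frame(lw_ratio = c(1.45, 1.40, 1.10, 1.42),
                    group = c("Shilo", "Shilo", "BeitEl", "BeitEl"))
  s <- sort_seeds(tab, curve)
  expect_identical(s$summary$n, c(2L, 2L))
  expect_identical(
    s$summary$n_accepted[s$summary$group == "BeitEl"], 1L)
})
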