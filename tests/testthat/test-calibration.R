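# The device's current-calibration design: set points of Table form
# (10 levels, 5 repetitions)
current_design <- c(15, 20, 30, 40, 50, 60, 70, 80, 90, 100)

test_that("constant-variance fit recovers noiseless lines exactly and reports 2-sigma uncertainty", {
  set.seed(1)
  d <- simulate_calibration(current_design, 5, intercept = 0.5, slope = 0.9, sd = 0)
  fit <- fit_linear(d)
  expect_equal(fit$slope, 0.9, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)
  expect_equal(fit$dof, 48)
  # the 95 % uncertainty convention: 2 * sigma_hat (0.1381 uA -> +/- 0.28 uA)
  expect_equal(round(2 * 0.1381, 2), 0.28)
  d2 <- simulate_calibration(current_design, 5, 0.5, 0.9, sd = 0.1381)
  fit2 <- fit_linear(d2)
  expect_equal(fit2$uncertainty_95, 2 * fit2$residual_sd)
  expect_error(fit_linear(calibration_dataset(rep(c(1, 2), each = 3),
                                              rnorm(6))), "distinct")
})

test_that("Monte-Carlo parameter recovery is unbiased at the bench design", {
  set.seed(42)
  reps <- 500
  est <- t(replicate(reps, {
    f <- fit_linear(simulate_calibration(current_design, 5, 0.49, 0.89, 0.14))
    c(f$intercept, f$slope)
  }))
  se <- apply(est, 2, stats::sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - 0.49), 3 * se[1])
  expect_lt(abs(mean(est[, 2]) - 0.89), 3 * se[2])
})

test_that("constant-variance diagnostic flags proportional noise and passes homoscedastic data", {
  set.seed(5)
  d_ok <- simulate_calibration(current_design, 5, 0.5, 0.9, sd = 0.14)
  f_ok <- fit_linear(d_ok)
  expect_false(check_constant_variance(d_ok, f_ok)$flagged)
  d_prop <- simulate_calibration(current_design, 5, 0.5, 0.9, sd = 0.05,
                                 model = "proportional")
  f_prop <- fit_linear(d_prop)
  expect_true(check_constant_variance(d_prop, f_prop)$flagged)
  d0 <- simulate_calibration(current_design, 5, 0.5, 0.9, sd = 0)
  expect_equal(check_constant_variance(d0, fit_linear(d0))$trend, 0)
})

test_that("proportional-variance fit swaps the transformed coefficients back correctly", {
  set.seed(9)
  d0 <- simulate_calibration(current_design, 5, 0, 0.9, sd = 0)
  f0 <- fit_proportional(d0)
  expect_equal(f0$slope, 0.9, tolerance = 1e-12)
  expect_equal(f0$intercept, 0, tolerance = 1e-10)
  reps <- 500
  est <- t(replicate(reps, {
    f <- fit_proportional(simulate_calibration(current_design, 5, 0.44, 0.89,
                                               sd = 0.011, model = "proportional"))
    c(f$intercept, f$slope)
  }))
  se <- apply(est, 2, stats::sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - 0.44), 3 * se[1])
  expect_lt(abs(mean(est[, 2]) - 0.89), 3 * se[2])
  expect_error(fit_proportional(calibration_dataset(rep(c(0, 1, 2), each = 2),
                                                    rnorm(6))), "positive")
})

test_that("inverse prediction inverts the calibration line", {
  ident <- structure(list(slope = 1, intercept = 0),
                     class = c("linear_calibration", "eit_calibration"))
  expect_equal(invert_calibration(ident, 5), 5)
  # printed coefficients for the 56.7 ohm load, target 50 uA
  t7 <- structure(list(slope = 0.8898, intercept = 0.4883),
                  class = c("linear_calibration", "eit_calibration"))
  expect_equal(invert_calibration(t7, 50), (50 - 0.4883) / 0.8898)
  expect_equal(invert_calibration(t7, 50), 55.6436, tolerance = 1e-4)
  # round trip through the forward model, noiseless
  d <- simulate_calibration(current_design, 5, 0.49, 0.89, sd = 0)
  f <- fit_linear(d)
  expect_equal(invert_calibration(f, predict(f, 63)), 63, tolerance = 1e-9)
  bad <- structure(list(slope = 0, intercept = 1),
                   class = c("linear_calibration", "eit_calibration"))
  expect_error(invert_calibration(bad, 1), "[Ss]ingular")
})

test_that("the combined voltage chain equals the composition of its stages", {
  # identity chain
  id <- combine_voltage_chain(c(0, 1), c(0, 1), c(0, 1), gains = c(1, 1))
  expect_equal(id$combined_slope, 1)
  expect_equal(id$combined_intercept, 0)
  expect_equal(apply_voltage_calibration(id, 0.42), 0.42)
  # printed three-stage coefficients with nominal gains
  g <- c(12, 8)
  t9 <- combine_voltage_chain(w = c(-0.0002, 0.7873), x = c(-0.021, 0.989),
                              y = c(-0.0006, 0.9897), gains = g)
  expect_equal(t9$combined_slope, g[1] * g[2] * 0.9897 * 0.989 * 0.7873)
  # exact algebraic identity with sequential stage application, random params
  set.seed(3)
  for (i in 1:20) {
    w <- rnorm(2); x <- rnorm(2); y <- rnorm(2); gg <- runif(2, 0.5, 20)
    ch <- combine_voltage_chain(w, x, y, gg)
    v <- rnorm(1)
    w_out <- gg[1] * (w[1] + w[2] * v)          # stage indications are output/gain
    x_out <- gg[2] * (x[1] + x[2] * w_out)
    y_out <- y[1] + y[2] * x_out
    expect_equal(ch$combined_intercept + ch$combined_slope * v, y_out,
                 tolerance = 1e-12)
    expect_equal(predict_voltage_chain(ch, v), y_out, tolerance = 1e-12)
  }
})

test_that("fitted three-stage chains recover a known transfer function", {
  set.seed(8)
  gains <- c(10, 5)
  v <- seq(0.0002, 0.02, length.out = 10)        # applied input voltages
  truth <- list(w = c(0.0001, 0.79), x = c(-0.002, 0.99), y = c(0.001, 0.99))
  reps <- 5
  mk <- function(ref, int, slope, sd)
    calibration_dataset(rep(ref, each = reps),
                        int + slope * rep(ref, each = reps) +
                          rnorm(length(ref) * reps, 0, sd))
  w_mean <- truth$w[1] + truth$w[2] * v
  x_mean <- truth$x[1] + truth$x[2] * (gains[1] * w_mean)
  ch <- fit_voltage_chain(mk(v, truth$w[1], truth$w[2], 2e-5),
                          mk(gains[1] * w_mean, truth$x[1], truth$x[2], 2e-4),
                          mk(gains[2] * x_mean, truth$y[1], truth$y[2], 2e-4),
                          gains)
  truth_ch <- combine_voltage_chain(truth$w, truth$x, truth$y, gains)
  expect_equal(ch$combined_slope, truth_ch$combined_slope, tolerance = 0.02)
  # inverse prediction recovers true inputs across the range
  rep_v <- predict_voltage_chain(truth_ch, v)
  est <- apply_voltage_calibration(ch, rep_v)
  fit <- stats::lm(est ~ v)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.02)
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 2e-4)
})

test_that("gain planning selects codes hitting the target under the full-scale constraint", {
  ch <- combine_voltage_chain(c(0, 1), c(0, 1), c(0, 1), gains = c(1, 1))
  # the device policy: amplify the largest channel to ~90 % of full scale
  plan <- plan_gains(ch, expected_input = 1e-3, target_reported = 0.9 * 3.3)
  expect_true(plan$feasible)
  expect_equal(plan$achieved, 2.97, tolerance = 0.01)
  expect_lte(plan$achieved, 3.3)
  expect_equal(plan$total_gain, plan$achieved / 1e-3, tolerance = 1e-6)
  # a 3000x target is achievable within one code step of the grid
  plan2 <- plan_gains(ch, 1e-3, 3.0)
  expect_true(plan2$feasible)
  expect_lt(abs(plan2$achieved - 3.0) / 3.0, 0.01)
  # unreachable low target: minimum gain is ~1x per stage
  plan3 <- plan_gains(ch, 1.0, 0.5)
  expect_false(plan3$feasible)
  expect_equal(plan3$code1, 255)     # max resistance = min gain
  expect_equal(plan3$code2, 255)
})
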