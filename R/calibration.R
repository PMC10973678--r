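#' Calibration dataset of repeated measurements at reference set points
#'
#' A calibration run steps a reference quantity (a current set point in uA,
#' or an applied voltage in V) through a series of levels and records
#' repeated indications of the measurement system at each level.
#'
#' @param reference Reference value for each measurement (recycled against
#'   `value` when `value` is a matrix of repetitions), or a data frame with
#'   columns `reference` and `value` (and optionally `rep`).
#' @param value Measured indications, one per row of the dataset.
#' @param load_label Optional label (e.g. the test load in ohms).
#' @return Object of class `calibration_dataset`: a data frame with columns
#'   `reference` and `value`.
#' @examples
#' d <- calibration_dataset(rep(c(10, 20, 30), each = 2),
#'                          c(9.9, 10.2, 19.8, 20.1, 30.2, 29.9))
#' @export
calibration_dataset <- function(reference, value = NULL, load_label = NULL) {
  if (is.data.frame(reference)) {
    df <- reference
    if (!all(c("reference", "value") %in% names(df)))
      stop("data frame input needs columns 'reference' and 'value'", call. = FALSE)
    df <- data.frame(reference = df$reference, value = df$value)
  } else {
    df <- data.frame(reference = as.numeric(reference), value = as.numeric(value))
  }
  if (anyNA(df)) stop("calibration data must not contain NA", call. = FALSE)
  ux <- unique(df$reference)
  if (length(ux) < 3)
    stop("calibration needs at least 3 distinct reference values", call. = FALSE)
  reps <- table(df$reference)
  if (any(reps < 2))
    stop("calibration needs at least 2 repetitions per reference value", call. = FALSE)
  attr(df, "load_label") <- load_label
  class(df) <- c("calibration_dataset", "data.frame")
  df
}

#' Fit the constant-variance linear calibration model
#'
#' Ordinary least squares of indication on reference over all repeated
#' measurements: `y = b0 + b1 x + e`, with the residual deviations assumed
#' i.i.d. normal with constant standard deviation. The residual standard
#' deviation uses `n - 2` degrees of freedom pooled over all repetitions,
#' and the 95 % measurement uncertainty is reported as `2 * sigma_hat`
#' (the device characterization convention; e.g. sigma_hat = 0.1381 uA
#' gives +/- 0.28 uA). Per-reference residual standard deviations are kept
#' for the constant-variance diagnostic.
#'
#' @param data A [calibration_dataset()].
#' @return Object of class `c("linear_calibration", "eit_calibration")`
#'   with elements `slope`, `intercept`, `residual_sd`, `dof`,
#'   `uncertainty_95`, `slope_se`, `intercept_se`, `per_reference_sd`,
#'   `fitted`, `residuals`, `data`.
#' @seealso [invert_calibration()], [check_constant_variance()]
#' @export
fit_linear <- function(data) {
  stopifnot(inherits(data, "calibration_dataset"))
  fit <- stats::lm(value ~ reference, data = data)
  if (stats::sd(data$reference) == 0 || any(is.na(stats::coef(fit))))
    stop("reference values are rank deficient", call. = FALSE)
  sm <- suppressWarnings(summary(fit))   # noiseless fits are legitimate
  sigma <- sm$sigma
  per_ref <- tapply(stats::residuals(fit), data$reference, stats::sd)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = sigma,
                 dof = fit$df.residual,
                 uncertainty_95 = 2 * sigma,
                 slope_se = sm$coefficients["reference", "Std. Error"],
                 intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
                 per_reference_sd = per_ref,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 data = data),
            class = c("linear_calibration", "eit_calibration"))
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat("Linear calibration (constant residual SD)\n")
  cat(sprintf("  slope: %.4f  intercept: %.4f  sigma_hat: %.4f  (95%% uncertainty: +/- %.2f)\n",
              x$slope, x$intercept, x$residual_sd, x$uncertainty_95))
  invisible(x)
}

#' @export
coef.linear_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.linear_calibration <- function(object, reference, ...) {
  object$intercept + object$slope * reference
}

#' Diagnostic for the constant-residual-variance assumption
#'
#' The constant-variance model is inappropriate when the dispersion of the
#' residuals grows with the fitted value (indication proportional noise).
#' The trend statistic is the Pearson correlation between the absolute
#' residuals and the fitted values; it is 0 for noiseless data and flags a
#' violation above `threshold`.
#'
#' @param data The [calibration_dataset()] used for the fit.
#' @param fit The [fit_linear()] result.
#' @param threshold Trend statistic above which the assumption is flagged.
#' @return List with `trend`, `flagged`, `per_reference_sd`, `fitted`,
#'   `residuals`.
#' @export
check_constant_variance <- function(data, fit, threshold = 0.3) {
  stopifnot(inherits(fit, "linear_calibration"))
  r <- fit$residuals
  scale <- max(abs(fit$fitted), 1)
  degenerate <- stats::sd(abs(r)) <= 1e-10 * scale || stats::sd(fit$fitted) == 0
  trend <- if (degenerate) 0 else stats::cor(abs(r), fit$fitted)
  list(trend = trend, flagged = trend > threshold,
       per_reference_sd = fit$per_reference_sd,
       fitted = fit$fitted, residuals = r)
}

#' Fit the proportional-variance calibration model
#'
#' When residual dispersion is proportional to the reference value, the
#' model `y = y0 + y1 x + eta` (Var(eta) proportional to x^2) is
#' transformed by dividing through by x: `y/x = y0 * (1/x) + y1 + eta/x`,
#' which has constant residual variance and is fitted by ordinary
#' (unweighted) least squares of `y/x` on `1/x`. The transformed fit's
#' intercept estimates the slope `y1` of the original model and its slope
#' estimates the intercept `y0`.
#'
#' @param data A [calibration_dataset()] with strictly positive reference
#'   values.
#' @return Object of class
#'   `c("proportional_calibration", "eit_calibration")` with elements
#'   `slope` (y1), `intercept` (y0), `relative_sd` (residual SD of the
#'   transformed fit, a dimensionless fraction of the reference),
#'   `uncertainty_95_relative` (2 * relative_sd), `dof`, `data`.
#' @export
fit_proportional <- function(data) {
  stopifnot(inherits(data, "calibration_dataset"))
  if (any(data$reference <= 0))
    stop("proportional-variance model requires strictly positive reference values",
         call. = FALSE)
  ty <- data$value / data$reference
  tx <- 1 / data$reference
  fit <- stats::lm(ty ~ tx)
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[1]),      # transformed intercept = y1
                 intercept = unname(stats::coef(fit)[2]),  # transformed slope = y0
                 relative_sd = sm$sigma,
                 uncertainty_95_relative = 2 * sm$sigma,
                 dof = fit$df.residual,
                 transformed_fitted = stats::fitted(fit),
                 transformed_residuals = stats::residuals(fit),
                 data = data),
            class = c("proportional_calibration", "eit_calibration"))
}

#' @export
print.proportional_calibration <- function(x, ...) {
  cat("Proportional-variance calibration\n")
  cat(sprintf("  slope (y1): %.4f  intercept (y0): %.4f  relative SD: %.4f  (95%%: +/- %.2f %%)\n",
              x$slope, x$intercept, x$relative_sd, 100 * x$uncertainty_95_relative))
  invisible(x)
}

#' @export
coef.proportional_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.proportional_calibration <- function(object, reference, ...) {
  object$intercept + object$slope * reference
}

#' Inverse prediction from a fitted calibration
#'
#' Estimates the reference set point that would produce a desired mean
#' indication: `x* = (y_bar - intercept) / slope`.
#'
#' @param fit A fitted calibration (`linear_calibration` or
#'   `proportional_calibration`).
#' @param desired_mean_output Target mean indication.
#' @return Estimated reference value.
#' @examples
#' # Printed device coefficients for the 56.7 ohm load:
#' fit <- list(slope = 0.8898, intercept = 0.4883)
#' class(fit) <- c("linear_calibration", "eit_calibration")
#' invert_calibration(fit, 50)  # set point needed for a 50 uA output
#' @export
invert_calibration <- function(fit, desired_mean_output) {
  stopifnot(inherits(fit, "eit_calibration"))
  if (!is.finite(fit$slope) || fit$slope == 0)
    stop("singular calibration: slope is zero", call. = FALSE)
  (desired_mean_output - fit$intercept) / fit$slope
}

#' Fit the three-stage voltage measurement chain
#'
#' The device's voltage path is calibrated in three stages: input voltage
#' to first amplifier stage (indication = externally measured G1 output
#' divided by the nominal gain G1), first to second stage (G2 output
#' divided by G2), and second stage to the device-reported voltage. Each
#' stage gets an independent constant-variance linear fit, and the three
#' are composed into a single end-to-end model
#' `reported = combined_intercept + combined_slope * input` with
#' `combined_slope = G1 G2 y1 x1 w1` and
#' `combined_intercept = y0 + y1 G2 x0 + G1 G2 y1 x1 w0`.
#'
#' @param stage_w [calibration_dataset()] for input -> G1 (reference =
#'   input voltage, value = measured G1 output / G1).
#' @param stage_x [calibration_dataset()] for G1 -> G2 (reference = G1
#'   output, value = measured G2 output / G2).
#' @param stage_y [calibration_dataset()] for G2 -> reported (reference =
#'   G2 output, value = device-reported voltage).
#' @param gains Numeric `c(G1, G2)` nominal amplifier gains.
#' @return Object of class `voltage_chain_calibration` with the three
#'   stage fits, the gains, `combined_slope` and `combined_intercept`.
#' @export
fit_voltage_chain <- function(stage_w, stage_x, stage_y, gains) {
  stopifnot(length(gains) == 2, all(gains > 0))
  fw <- fit_linear(stage_w)
  fx <- fit_linear(stage_x)
  fy <- fit_linear(stage_y)
  combine_voltage_chain(
    w = c(fw$intercept, fw$slope), x = c(fx$intercept, fx$slope),
    y = c(fy$intercept, fy$slope), gains = gains,
    stages = list(w = fw, x = fx, y = fy))
}

#' @rdname fit_voltage_chain
#' @param w,x,y Numeric `c(intercept, slope)` per stage, when the stage
#'   coefficients are already known (e.g. from a printed calibration
#'   table).
#' @param stages Optional list of stage fits to carry along.
#' @export
combine_voltage_chain <- function(w, x, y, gains, stages = NULL) {
  g1 <- gains[1]; g2 <- gains[2]
  w0 <- w[1]; w1 <- w[2]; x0 <- x[1]; x1 <- x[2]; y0 <- y[1]; y1 <- y[2]
  structure(list(stage_w = c(intercept = w0, slope = w1),
                 stage_x = c(intercept = x0, slope = x1),
                 stage_y = c(intercept = y0, slope = y1),
                 gains = c(G1 = g1, G2 = g2),
                 combined_slope = g1 * g2 * y1 * x1 * w1,
                 combined_intercept = y0 + y1 * g2 * x0 + g1 * g2 * y1 * x1 * w0,
                 stages = stages),
            class = "voltage_chain_calibration")
}

#' @export
print.voltage_chain_calibration <- function(x, ...) {
  cat("Voltage measurement chain calibration\n")
  cat(sprintf("  gains: G1 = %.4g, G2 = %.4g\n", x$gains[1], x$gains[2]))
  cat(sprintf("  combined: reported = %.6g + %.6g * input\n",
              x$combined_intercept, x$combined_slope))
  invisible(x)
}

#' Forward-predict the reported voltage through the chain model
#'
#' @param chain A `voltage_chain_calibration`.
#' @param input Input voltage(s).
#' @param gains Optional gains overriding the chain's nominal gains (used
#'   when planning gain settings).
#' @return Predicted device-reported voltage(s).
#' @export
predict_voltage_chain <- function(chain, input, gains = chain$gains) {
  g1 <- gains[1]; g2 <- gains[2]
  w0 <- chain$stage_w[1]; w1 <- chain$stage_w[2]
  x0 <- chain$stage_x[1]; x1 <- chain$stage_x[2]
  y0 <- chain$stage_y[1]; y1 <- chain$stage_y[2]
  unname(y0 + y1 * g2 * x0 + g1 * g2 * y1 * x1 * w0 +
           g1 * g2 * y1 * x1 * w1 * input)
}

#' Estimate the true input voltage from a reported voltage
#'
#' Inverse prediction through the combined chain model:
#' `v* = (reported - combined_intercept) / combined_slope`.
#'
#' @param chain A `voltage_chain_calibration`.
#' @param reported Device-reported voltage(s).
#' @return Input-voltage estimate(s).
#' @export
apply_voltage_calibration <- function(chain, reported) {
  stopifnot(inherits(chain, "voltage_chain_calibration"))
  if (!is.finite(chain$combined_slope) || chain$combined_slope == 0)
    stop("singular calibration: combined slope is zero", call. = FALSE)
  (reported - chain$combined_intercept) / chain$combined_slope
}

#' Select discrete amplifier gain codes for a target reported voltage
#'
#' Exhaustive search over the two digital potentiometer code grids
#' (256 x 256 at defaults) for the pair of gain settings whose predicted
#' reported voltage is closest to the target without exceeding the ADC
#' full scale. Ties are broken deterministically toward the lower total
#' gain. The device's gain-tuning goal is to amplify the largest channel
#' to close to the ADC full scale (a 90 % headroom policy on a 3.3 V
#' converter targets 2.97 V).
#'
#' @param chain A `voltage_chain_calibration` (stage models are reused
#'   with the candidate gains in place of the nominal ones).
#' @param expected_input Expected input voltage (> 0).
#' @param target_reported Desired reported voltage (within the ADC range).
#' @param pot An [amplifier_chain()] describing the potentiometers.
#' @param full_scale ADC full-scale voltage.
#' @return List with `code1`, `code2` (0-based potentiometer codes),
#'   `gain1`, `gain2`, `total_gain`, `achieved` (predicted reported
#'   voltage), and `feasible` (`FALSE` when the target lies outside the
#'   achievable range, in which case the closest achievable setting is
#'   returned).
#' @export
plan_gains <- function(chain, expected_input, target_reported,
                       pot = amplifier_chain(), full_scale = 3.3) {
  stopifnot(inherits(chain, "voltage_chain_calibration"),
            expected_input > 0, target_reported <= full_scale)
  codes <- 0:(pot$pot_steps - 1L)
  rg <- pot$wiper + codes * pot$pot_max / (pot$pot_steps - 1L)
  g <- stage_gain(rg, pot$gain_constant)
  # predicted reported voltage is affine in (g1*g2) and in g2 alone:
  w0 <- chain$stage_w[1]; w1 <- chain$stage_w[2]
  x0 <- chain$stage_x[1]; x1 <- chain$stage_x[2]
  y0 <- chain$stage_y[1]; y1 <- chain$stage_y[2]
  g1g2 <- outer(g, g)                                  # [code1, code2]
  g2m <- matrix(g, nrow = pot$pot_steps, ncol = pot$pot_steps, byrow = TRUE)
  pred <- unname(y0 + y1 * g2m * x0 +
                   g1g2 * (y1 * x1 * w0 + y1 * x1 * w1 * expected_input))
  ok <- pred <= full_scale
  err <- abs(pred - target_reported)
  pick <- function(mask) {
    idx <- which(mask)
    e <- err[idx]
    best <- idx[e == min(e)]
    best[which.min(g1g2[best])]          # tie-break: lower total gain
  }
  feasible_any <- any(ok)
  i <- if (feasible_any) pick(ok) else pick(!logical(length(err)))
  code1 <- (i - 1L) %% pot$pot_steps
  code2 <- (i - 1L) %/% pot$pot_steps
  achieved <- pred[i]
  in_range <- feasible_any &&
    target_reported >= min(pred[ok]) - .Machine$double.eps^0.5 &&
    target_reported <= max(pred[ok]) + .Machine$double.eps^0.5
  list(code1 = code1, code2 = code2,
       gain1 = g[code1 + 1L], gain2 = g[code2 + 1L],
       total_gain = g[code1 + 1L] * g[code2 + 1L],
       achieved = achieved, feasible = in_range)
}

#' Simulate a calibration dataset from known model parameters
#'
#' Generates repeated indications at given reference set points under
#' either the constant-variance or the proportional-variance noise model;
#' used for calibration parameter-recovery studies.
#'
#' @param reference_values Distinct reference set points.
#' @param repetitions Repetitions per set point.
#' @param intercept,slope True model parameters.
#' @param sd Residual SD: absolute (constant model) or as a fraction of
#'   the reference value (proportional model).
#' @param model `"constant"` or `"proportional"`.
#' @return A [calibration_dataset()].
#' @export
simulate_calibration <- function(reference_values, repetitions = 5,
                                 intercept = 0, slope = 1, sd = 0.1,
                                 model = c("constant", "proportional")) {
  model <- match.arg(model)
  x <- rep(reference_values, each = repetitions)
  noise_sd <- if (model == "constant") rep(sd, length(x)) else sd * x
  y <- intercept + slope * x + stats::rnorm(length(x), 0, noise_sd)
  calibration_dataset(x, y)
}
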