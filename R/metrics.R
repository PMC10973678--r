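#' Channel time series container
#'
#' A frames-by-channels matrix of demodulated magnitudes with strictly
#' increasing frame timestamps; each fixed drive/measure quadruple tracked
#' across frames is one channel.
#'
#' @param frames Numeric matrix, frames x channels.
#' @param timestamps Frame times in seconds (default: one frame per
#'   second).
#' @return Object of class `channel_series`.
#' @export
channel_series <- function(frames, timestamps = seq_len(nrow(frames)) - 1) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 2)
    stop("channel series needs at least 2 frames", call. = FALSE)
  if (length(timestamps) != nrow(frames) || any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing, one per frame", call. = FALSE)
  structure(list(frames = frames, timestamps = as.numeric(timestamps)),
            class = "channel_series")
}

as_channel_series <- function(x) {
  if (inherits(x, "channel_series")) x else channel_series(x)
}

#' Per-channel signal-to-noise ratio
#'
#' The ratio of each channel's mean to its standard deviation across
#' frames, expressed as a root-power quantity in decibels:
#' `20 * log10(mean / sd)`. A constant channel has infinite SNR.
#'
#' @param series A [channel_series()] or frames matrix.
#' @return Numeric vector of per-channel SNR in dB.
#' @export
channel_snr <- function(series) {
  series <- as_channel_series(series)
  mu <- colMeans(series$frames)
  s <- apply(series$frames, 2, stats::sd)
  out <- ifelse(s == 0, Inf, 20 * log10(mu / s))
  out
}

#' Per-channel accuracy against a simulated measurement
#'
#' Both vectors are independently min-max normalized to `[0, 1]`; the
#' accuracy of a channel is one minus the absolute difference of the
#' normalized values. Being min-max based, the measure is invariant to
#' independent affine rescaling of either input.
#'
#' @param measured_mean Mean background measurement per channel.
#' @param simulated Simulated (forward-model) measurement per channel.
#' @return Numeric vector of per-channel accuracies in `[0, 1]` (times
#'   100 gives percent).
#' @export
channel_accuracy <- function(measured_mean, simulated) {
  if (length(measured_mean) != length(simulated))
    stop("vectors must have equal length", call. = FALSE)
  norm01 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) stop("cannot normalize a constant vector", call. = FALSE)
    (v - r[1]) / (r[2] - r[1])
  }
  1 - abs(norm01(measured_mean) - norm01(simulated))
}

#' Non-overlapping Allan deviation per channel
#'
#' The two-sample (Allan) deviation over averaging windows of width tau:
#' the series is cut into consecutive non-overlapping bins of tau seconds,
#' each bin is averaged, and
#' `sigma_y(tau) = sqrt(0.5 * mean(diff(bin_means)^2))`. White noise
#' decays as tau^(-1/2); drift makes the curve rise again at long tau.
#'
#' @param series A [channel_series()] (uniformly sampled).
#' @param taus Averaging windows in seconds. Windows longer than half the
#'   record are dropped with a warning.
#' @return List with `tau` (windows kept) and `adev` (matrix, windows x
#'   channels).
#' @export
allan_deviation <- function(series, taus) {
  series <- as_channel_series(series)
  dt <- stats::median(diff(series$timestamps))
  n <- nrow(series$frames)
  span <- n * dt
  keep <- taus <= span / 2 & taus >= dt
  if (!all(keep)) warning("dropping tau values longer than half the record (or shorter than the frame period)")
  taus <- taus[keep]
  adev <- matrix(NA_real_, length(taus), ncol(series$frames))
  for (ti in seq_along(taus)) {
    m <- max(1L, round(taus[ti] / dt))
    k <- floor(n / m)
    idx <- rep(seq_len(k), each = m)
    means <- apply(series$frames[seq_len(k * m), , drop = FALSE], 2,
                   function(col) tapply(col, idx, mean))
    adev[ti, ] <- sqrt(0.5 * colMeans(diff(means)^2))
  }
  list(tau = taus, adev = adev)
}

#' Per-channel drift over a time span
#'
#' The percentage change between the mean over a window at the start of
#' the record and the mean over an equal window a fixed span later:
#' `100 * (mean_late - mean_early) / mean_early`.
#'
#' @param series A [channel_series()].
#' @param window Averaging window length in seconds.
#' @param span Time offset between the two windows in seconds.
#' @return Numeric vector of per-channel drift in percent.
#' @export
drift <- function(series, window, span) {
  series <- as_channel_series(series)
  t <- series$timestamps
  t0 <- t[1]
  dt <- stats::median(diff(t))
  if (t0 + span + window > t[length(t)] + dt + 1e-9)
    stop("record does not cover span + window", call. = FALSE)
  early <- t >= t0 & t < t0 + window
  late <- t >= t0 + span & t < t0 + span + window
  m1 <- colMeans(series$frames[early, , drop = FALSE])
  m2 <- colMeans(series$frames[late, , drop = FALSE])
  100 * (m2 - m1) / m1
}

#' Threshold region of interest of a reconstruction image
#'
#' Pixels of value greater than one fourth of the image maximum.
#'
#' @param grid A rasterized pixel grid (see [rasterize()]) or an
#'   `eit_image` (rasterized at 64 x 64).
#' @param threshold_fraction Fraction of the maximum (default 1/4).
#' @return Logical matrix of the same shape (FALSE outside the disk),
#'   with the threshold stored in `attr(, "threshold")`.
#' @export
roi_mask <- function(grid, threshold_fraction = 0.25) {
  if (inherits(grid, "eit_image")) grid <- rasterize(grid)
  mx <- max(grid, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("image has no positive pixels; ROI is empty", call. = FALSE)
  mask <- !is.na(grid) & grid > threshold_fraction * mx
  attr(mask, "threshold") <- threshold_fraction * mx
  mask
}

#' Detectability of a target in a reconstruction image
#'
#' The ratio of the mean to the standard deviation of the pixels inside
#' the thresholded region of interest, in decibels
#' (`20 * log10(mean / sd)`). A perfectly uniform ROI gives `Inf`.
#'
#' @param grid A rasterized pixel grid or `eit_image`.
#' @param mask Optional precomputed [roi_mask()].
#' @return Detectability in dB.
#' @export
detectability <- function(grid, mask = NULL) {
  if (inherits(grid, "eit_image")) grid <- rasterize(grid)
  if (is.null(mask)) mask <- roi_mask(grid)
  px <- grid[mask]
  if (!length(px)) stop("empty region of interest", call. = FALSE)
  s <- stats::sd(px)
  if (length(px) < 2 || s == 0) return(Inf)
  20 * log10(mean(px) / s)
}

#' Distinguishability of a target against a reference object
#'
#' The same statistic as [detectability()], computed on an image
#' reconstructed against a reference frame that already contains the
#' object from which the targets are to be distinguished (rather than an
#' empty background). With an empty-bath reference it reduces to
#' detectability.
#'
#' @inheritParams detectability
#' @return Distinguishability in dB.
#' @export
distinguishability <- function(grid, mask = NULL) {
  detectability(grid, mask)
}

in_disk_mask <- function(grid) !is.na(grid)

roi_centre_of_mass <- function(grid, mask) {
  w <- grid[mask]
  xs <- matrix(attr(grid, "x"), nrow = nrow(grid), ncol = ncol(grid))[mask]
  ys <- matrix(attr(grid, "y"), nrow = nrow(grid), ncol = ncol(grid),
               byrow = TRUE)[mask]
  c(x = sum(w * xs) / sum(w), y = sum(w * ys) / sum(w))
}

#' GREIT figures of merit
#'
#' Standardized image-quality measures comparing a measured
#' reconstruction to a simulated (noiseless forward-model) reconstruction
#' of the same configuration:
#' * amplitude: mean of the in-disk pixel values (set
#'   `amplitude_roi_only = TRUE` to average the ROI pixels instead);
#' * position error: distance of the measured image's ROI-weighted centre
#'   of mass from the bath centre, minus the same distance for the
#'   reference image;
#' * resolution: square root of the ROI pixel area over the in-disk pixel
#'   area;
#' * ringing: total magnitude of negative pixels outside the ROI over the
#'   total of positive pixels inside it.
#'
#' @param grid Measured reconstruction (pixel grid or `eit_image`).
#' @param reference Simulated reconstruction of the same configuration on
#'   the same grid.
#' @param amplitude_roi_only Average only the ROI pixels for the
#'   amplitude measure.
#' @return Named list: `amplitude`, `position_error`, `resolution`,
#'   `ringing`.
#' @export
figures_of_merit <- function(grid, reference, amplitude_roi_only = FALSE) {
  if (inherits(grid, "eit_image")) grid <- rasterize(grid)
  if (inherits(reference, "eit_image")) reference <- rasterize(reference)
  if (!identical(dim(grid), dim(reference)))
    stop("images must be rasterized on the same grid", call. = FALSE)
  mask <- roi_mask(grid)
  ref_mask <- roi_mask(reference)
  disk <- in_disk_mask(grid)
  amplitude <- if (amplitude_roi_only) mean(grid[mask]) else mean(grid[disk])
  com <- roi_centre_of_mass(grid, mask)
  com_ref <- roi_centre_of_mass(reference, ref_mask)
  position_error <- sqrt(sum(com^2)) - sqrt(sum(com_ref^2))
  resolution <- sqrt(sum(mask) / sum(disk))
  outside_neg <- grid[disk & !mask]
  ringing_num <- sum(abs(outside_neg[outside_neg < 0]))
  ringing_den <- sum(grid[mask][grid[mask] > 0])
  list(amplitude = amplitude, position_error = position_error,
       resolution = resolution,
       ringing = if (ringing_den > 0) ringing_num / ringing_den else NA_real_)
}
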