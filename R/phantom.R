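#' Synthetic salt-bath phantom session
#'
#' Describes one emulated bench session on the circular salt-bath
#' phantom: bath geometry, electrode count, background conductivity,
#' target configurations, frame counts and timing, and the per-channel
#' noise and drift levels. The generator is the source of all synthetic
#' measurement data and is deterministic under a fixed seed.
#'
#' Noise is multiplicative per channel: each channel draws a true SNR
#' uniformly from the session's band narrowed by `snr_guard_db` on both
#' sides (so the SNR *estimated* from a finite number of frames still
#' falls inside the nominal band), and Gaussian noise with
#' `sd = mean / 10^(SNR/20)` is added. Drift is a shared multiplicative
#' random walk across frames with per-frame step `drift_step`; the
#' default step reproduces a mean absolute drift of about 0.25 % over
#' 30 min at one frame per second.
#'
#' @param configs List of target configurations; each is a list with
#'   `name` and `targets` (data frame with columns `x`, `y`, `diameter`,
#'   `ratio`; zero rows for an empty bath).
#' @param bath_radius Bath radius in mm.
#' @param n_electrodes Electrode count.
#' @param electrode_width Electrode width in mm (informational; the
#'   forward model uses point electrodes).
#' @param background_resistivity Bath resistivity in ohm-m (0.194 for the
#'   36.7 g/L saline).
#' @param frames_per_config Frames collected per configuration.
#' @param snr_band_db Channel SNR band in dB the device exhibits.
#' @param snr_guard_db Guard subtracted from both band edges when drawing
#'   per-channel SNRs.
#' @param drift_step Per-frame SD of the shared random-walk drift
#'   (fractional).
#' @param frame_rate Frames per second.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return Object of class `phantom_session`.
#' @export
phantom_session <- function(configs,
                            bath_radius = 120, n_electrodes = 16L,
                            electrode_width = 4.6,
                            background_resistivity = 0.194,
                            frames_per_config = 20L,
                            snr_band_db = c(36, 63), snr_guard_db = 3,
                            drift_step = 7.4e-5,
                            frame_rate = 2, seed = 1L) {
  stopifnot(frames_per_config >= 1, bath_radius > 0,
            background_resistivity > 0, length(snr_band_db) == 2)
  for (cf in configs) {
    tg <- cf$targets
    if (is.null(tg) || nrow(tg) == 0) next
    if (any(sqrt(tg$x^2 + tg$y^2) + tg$diameter / 2 >= bath_radius))
      stop(sprintf("configuration '%s': target extends outside the bath", cf$name),
           call. = FALSE)
    if (nrow(tg) > 1) {
      for (i in seq_len(nrow(tg) - 1)) for (j in (i + 1):nrow(tg)) {
        sep <- sqrt((tg$x[i] - tg$x[j])^2 + (tg$y[i] - tg$y[j])^2)
        if (sep < (tg$diameter[i] + tg$diameter[j]) / 2)
          stop(sprintf("configuration '%s': overlapping targets", cf$name),
               call. = FALSE)
      }
    }
  }
  structure(list(configs = configs, bath_radius = bath_radius,
                 n_electrodes = as.integer(n_electrodes),
                 electrode_width = electrode_width,
                 background_resistivity = background_resistivity,
                 frames_per_config = as.integer(frames_per_config),
                 snr_band_db = snr_band_db, snr_guard_db = snr_guard_db,
                 drift_step = drift_step, frame_rate = frame_rate,
                 seed = as.integer(seed)),
            class = "phantom_session")
}

#' @export
print.phantom_session <- function(x, ...) {
  cat(sprintf("Phantom session: %d configuration(s), %d frames each, bath radius %g mm\n",
              length(x$configs), x$frames_per_config, x$bath_radius))
  invisible(x)
}

#' Standard single-target bench session
#'
#' A 50 mm insulating acrylic disk placed at 9 positions 20 mm apart
#' along one bath diameter (radial offsets -80 to 80 mm), 20 frames per
#' position, plus 20 empty-bath background frames. The outermost target
#' edge sits at 105 mm, inside the 120 mm bath.
#'
#' @param seed Session seed.
#' @param ... Overrides passed to [phantom_session()].
#' @return A `phantom_session`.
#' @export
standard_single_target_session <- function(seed = 1L, ...) {
  offsets <- seq(-80, 80, by = 20)
  configs <- c(
    list(list(name = "background",
              targets = data.frame(x = numeric(0), y = numeric(0),
                                   diameter = numeric(0), ratio = numeric(0)))),
    lapply(offsets, function(r)
      list(name = sprintf("single_r%+d", r),
           targets = data.frame(x = r, y = 0, diameter = 50, ratio = 1e-6))))
  phantom_session(configs, seed = seed, ...)
}

#' Standard two-target bench session
#'
#' Two insulating disks of half the single target's area (35.36 mm =
#' 50 / sqrt(2) diameter, combined area equal to the 50 mm target) placed
#' symmetrically about the centre along one diameter at 4
#' centre-to-centre separations in a 20 mm arithmetic sequence (40 to
#' 100 mm, the first just beyond touching), 20 frames each, plus an
#' empty-bath background and the single-object reference configuration
#' for distinguishability: the 50 mm target (the one object of the same
#' combined area from which the pairs are to be distinguished) at the
#' centre.
#'
#' @param seed Session seed.
#' @param separations Centre-to-centre separations in mm.
#' @param ... Overrides passed to [phantom_session()].
#' @return A `phantom_session`.
#' @export
standard_two_target_session <- function(seed = 1L,
                                        separations = c(40, 60, 80, 100),
                                        ...) {
  d <- 50 / sqrt(2)
  configs <- c(
    list(list(name = "background",
              targets = data.frame(x = numeric(0), y = numeric(0),
                                   diameter = numeric(0), ratio = numeric(0)))),
    list(list(name = "reference_single",
              targets = data.frame(x = 0, y = 0, diameter = 50, ratio = 1e-6))),
    lapply(separations, function(s)
      list(name = sprintf("pair_sep%d", round(s)),
           targets = data.frame(x = c(-s / 2, s / 2), y = c(0, 0),
                                diameter = d, ratio = 1e-6))))
  phantom_session(configs, seed = seed, ...)
}

#' Standard drift session
#'
#' A long empty-bath run (2 h at 1 frame/s by default) for the Allan
#' deviation and drift measures.
#'
#' @param seed Session seed.
#' @param duration Run length in seconds.
#' @param frame_rate Frames per second.
#' @param ... Overrides passed to [phantom_session()].
#' @return A `phantom_session`.
#' @export
standard_drift_session <- function(seed = 1L, duration = 7200,
                                   frame_rate = 1, ...) {
  configs <- list(list(name = "background",
                       targets = data.frame(x = numeric(0), y = numeric(0),
                                            diameter = numeric(0),
                                            ratio = numeric(0))))
  phantom_session(configs, frames_per_config = round(duration * frame_rate),
                  frame_rate = frame_rate, seed = seed, ...)
}

#' Generate measurement frames for a phantom session
#'
#' For each configuration the targets are painted onto the mesh (centroid
#' in target), the forward problem is solved for the noiseless
#' measurement vector, and `frames_per_config` noisy frames are drawn:
#' per-channel multiplicative Gaussian noise at the channel's drawn SNR,
#' plus a session-wide random-walk drift shared by all channels.
#' Configurations are generated in order, sharing one frame clock.
#'
#' @param session A [phantom_session()].
#' @param mesh A [build_disk_mesh()] mesh matching the session geometry.
#' @param protocol An `eit_protocol` for the session's electrode count.
#' @param current Drive current in amperes.
#' @param noise,drift_on Disable to obtain noiseless / drift-free frames.
#' @param gain Measurement gain applied to all frames. `"auto"` mirrors
#'   the device's gain-tuning policy: the largest background channel is
#'   amplified to 90 % of the ADC full scale (3.3 V), putting the
#'   magnitudes in the device's reported 0.19-1.5 V range. Use 1 for raw
#'   forward-model volts.
#' @param full_scale ADC full-scale voltage used by the auto gain policy.
#' @return Object of class `session_outputs`: list with `configs` (per
#'   configuration: `name`, `targets`, `noiseless` vector, `frames`
#'   matrix, `timestamps`), `channel_snr_db` (drawn per-channel SNRs),
#'   `gain`, `protocol`, `mesh`, `session`.
#' @export
generate_frames <- function(session, mesh, protocol, current = 98e-6,
                            noise = TRUE, drift_on = TRUE,
                            gain = "auto", full_scale = 3.3) {
  stopifnot(inherits(session, "phantom_session"), inherits(mesh, "disk_mesh"))
  if (mesh$n_electrodes != session$n_electrodes)
    stop("mesh electrode count does not match the session", call. = FALSE)
  if (abs(mesh$radius - session$bath_radius) > 1e-9)
    stop("mesh radius does not match the session bath", call. = FALSE)
  set.seed(session$seed)
  bg <- 1 / session$background_resistivity
  n_ch <- nrow(protocol)
  band <- sort(session$snr_band_db)
  lo <- band[1] + session$snr_guard_db
  hi <- band[2] - session$snr_guard_db
  snr_db <- stats::runif(n_ch, lo, hi)
  rel_sd <- 10^(-snr_db / 20)
  n_f <- session$frames_per_config
  clock <- 0
  drift_level <- 0
  noiseless <- lapply(session$configs, function(cf)
    solve_forward(mesh, paint_targets(mesh, bg, cf$targets), protocol, current))
  if (identical(gain, "auto"))
    gain <- 0.9 * full_scale / max(noiseless[[1]])
  out <- vector("list", length(session$configs))
  for (ci in seq_along(session$configs)) {
    cf <- session$configs[[ci]]
    v <- gain * noiseless[[ci]]
    frames <- matrix(0, n_f, n_ch)
    ts <- numeric(n_f)
    for (f in seq_len(n_f)) {
      drift_level <- drift_level +
        if (drift_on) stats::rnorm(1, 0, session$drift_step) else 0
      row <- v * (1 + drift_level)
      if (noise) row <- row + stats::rnorm(n_ch, 0, v * rel_sd)
      frames[f, ] <- row
      ts[f] <- clock
      clock <- clock + 1 / session$frame_rate
    }
    out[[ci]] <- list(name = cf$name, targets = cf$targets,
                      noiseless = v, frames = frames, timestamps = ts)
  }
  names(out) <- vapply(out, `[[`, "", "name")
  structure(list(configs = out, channel_snr_db = snr_db, gain = gain,
                 protocol = protocol, mesh = mesh, session = session),
            class = "session_outputs")
}

#' @export
print.session_outputs <- function(x, ...) {
  cat(sprintf("Session outputs: %d configuration(s) x %d frames x %d channels\n",
              length(x$configs), nrow(x$configs[[1]]$frames),
              ncol(x$configs[[1]]$frames)))
  invisible(x)
}

#' Serialize session frames to the device's ASCII stream format
#'
#' @param outputs A `session_outputs`.
#' @param config Configuration name (default: first).
#' @return A single character string of concatenated encoded frames.
#' @export
session_to_stream <- function(outputs, config = names(outputs$configs)[1]) {
  stopifnot(inherits(outputs, "session_outputs"))
  fr <- outputs$configs[[config]]$frames
  paste0(vapply(seq_len(nrow(fr)), function(i) encode_frame(fr[i, ]),
                character(1)), collapse = "")
}
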