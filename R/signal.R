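#' Excitation and sampling specification
#'
#' Describes the device's drive waveform and burst sampling scheme: a
#' 25 kHz sine synthesized by a DAC as a 16-level staircase with 0.6 V
#' peak-to-peak (0.21 V RMS), sampled by the ADC 10 times per cycle over
#' `n_cycles` cycles, with the first `discard_samples` samples dropped to
#' skip the post-multiplexer-switching transient (about 30 us long; 10
#' samples at 250 kHz give a 40 us guard).
#'
#' @param frequency Excitation frequency in Hz.
#' @param amplitude_pp Peak-to-peak drive amplitude in volts.
#' @param dac_levels DAC staircase levels per cycle (>= 2).
#' @param samples_per_cycle ADC samples per excitation cycle.
#' @param n_cycles Sampled cycles retained per measurement (1-10 on the
#'   device; default 10).
#' @param discard_samples Leading samples discarded.
#' @return An object of class `excitation_spec`.
#' @export
excitation_spec <- function(frequency = 25000, amplitude_pp = 0.6,
                            dac_levels = 16L, samples_per_cycle = 10L,
                            n_cycles = 10L, discard_samples = 10L) {
  stopifnot(frequency > 0, amplitude_pp >= 0, dac_levels >= 2,
            samples_per_cycle >= 2, n_cycles >= 1, discard_samples >= 0)
  structure(list(frequency = frequency, amplitude_pp = amplitude_pp,
                 dac_levels = as.integer(dac_levels),
                 samples_per_cycle = as.integer(samples_per_cycle),
                 n_cycles = as.integer(n_cycles),
                 discard_samples = as.integer(discard_samples)),
            class = "excitation_spec")
}

#' Synthesize the DAC staircase excitation waveform
#'
#' Zero-order-hold staircase approximation of a sine: `dac_levels` held
#' voltage levels per cycle, rescaled so the staircase spans exactly
#' `amplitude_pp` with zero mean. The sample phase is offset a quarter
#' step from the zero crossings so all levels within a cycle are distinct.
#' As `dac_levels` grows the waveform converges to an ideal sine (RMS ->
#' amplitude_pp / (2 sqrt 2)).
#'
#' @param spec An [excitation_spec()].
#' @param duration Waveform duration in seconds (>= one cycle).
#' @return A data frame with columns `time` (start of each hold interval)
#'   and `value` (held voltage); the hold duration is stored in
#'   `attr(, "hold")`.
#' @export
synth_excitation <- function(spec = excitation_spec(), duration = 1 / spec$frequency) {
  stopifnot(inherits(spec, "excitation_spec"))
  if (duration < 1 / spec$frequency)
    stop("duration must cover at least one excitation cycle", call. = FALSE)
  L <- spec$dac_levels
  base <- sin(2 * pi * ((0:(L - 1)) + 0.25) / L)
  span <- max(base) - min(base)
  levels <- if (spec$amplitude_pp > 0 && span > 0) base * spec$amplitude_pp / span else base * 0
  hold <- 1 / (spec$frequency * L)
  n <- floor(duration / hold + 1e-9)
  k <- 0:(n - 1)
  out <- data.frame(time = k * hold, value = levels[(k %% L) + 1L])
  attr(out, "hold") <- hold
  out
}

#' Simulate one burst-sampled measurement
#'
#' Samples a sinusoid of the excitation frequency at
#' `samples_per_cycle * frequency`, prepends a decaying switching transient
#' (exponential settling, default 10 us time constant) over the discard
#' interval, adds white Gaussian noise, and optionally quantizes through an
#' ADC model. Samples exceeding the ADC full scale are clipped and the
#' burst is flagged.
#'
#' @param spec An [excitation_spec()].
#' @param amplitude Signal amplitude (peak) in volts.
#' @param phase Signal phase in radians relative to the excitation.
#' @param noise_sd Additive noise standard deviation in volts.
#' @param adc Optional [adc_model()] applied to the samples.
#' @param transient_amplitude Initial amplitude of the switching transient
#'   (defaults to the signal amplitude).
#' @param transient_tau Transient settling time constant in seconds.
#' @return An object of class `eit_burst`: list with `samples`,
#'   `sample_rate`, `n_discard` (length of the transient-contaminated
#'   prefix to drop), `phase_reference` (excitation phase at the first
#'   retained sample), `frequency`, and `clipped`.
#' @seealso [trim_burst()], [iq_demodulate()]
#' @export
simulate_burst <- function(spec = excitation_spec(), amplitude, phase = 0,
                           noise_sd = 0, adc = NULL,
                           transient_amplitude = amplitude,
                           transient_tau = 10e-6) {
  stopifnot(inherits(spec, "excitation_spec"), amplitude >= 0)
  if (!is.null(adc) && amplitude > adc$full_scale)
    stop("amplitude exceeds ADC full scale", call. = FALSE)
  fs <- spec$frequency * spec$samples_per_cycle
  n <- spec$discard_samples + spec$n_cycles * spec$samples_per_cycle
  t <- (0:(n - 1)) / fs
  s <- amplitude * sin(2 * pi * spec$frequency * t + phase) +
    transient_amplitude * exp(-t / transient_tau)
  if (noise_sd > 0) s <- s + stats::rnorm(n, 0, noise_sd)
  clipped <- FALSE
  if (!is.null(adc)) {
    clipped <- any(abs(s) > adc$full_scale)
    s <- adc_quantize(adc, s)
  }
  structure(list(samples = s, sample_rate = fs,
                 n_discard = spec$discard_samples,
                 phase_reference = (2 * pi * spec$frequency *
                                      spec$discard_samples / fs) %% (2 * pi),
                 frequency = spec$frequency, clipped = clipped),
            class = "eit_burst")
}

#' Drop the transient-contaminated prefix of a burst
#'
#' @param burst An `eit_burst`.
#' @return The burst with its discard prefix removed (`n_discard = 0`);
#'   `phase_reference` already refers to the first retained sample so it is
#'   unchanged.
#' @export
trim_burst <- function(burst) {
  stopifnot(inherits(burst, "eit_burst"))
  if (burst$n_discard > 0) {
    burst$samples <- burst$samples[-seq_len(burst$n_discard)]
    burst$n_discard <- 0L
  }
  burst
}

#' I/Q demodulation of a sampled burst
#'
#' Correlates the retained samples with in-phase and quadrature reference
#' sinusoids at the excitation frequency and applies a simple mean as the
#' low-pass filter (the device firmware's choice): I = (2/N) sum s_k
#' sin(theta_k), Q = (2/N) sum s_k cos(theta_k), with theta_k advanced from
#' the burst's `phase_reference`. The 2/N scaling makes the magnitude
#' M = sqrt(I^2 + Q^2) equal the sinusoid's peak amplitude under coherent
#' sampling, and the phase is Phi = atan2(Q, I), in (-pi, pi].
#'
#' @param burst An `eit_burst` with the discard prefix already removed
#'   (see [trim_burst()]).
#' @param frequency Demodulation frequency in Hz (defaults to the burst's
#'   excitation frequency).
#' @return An object of class `iq_demod`: list with `in_phase`,
#'   `quadrature`, `magnitude`, `phase`.
#' @export
iq_demodulate <- function(burst, frequency = burst$frequency) {
  stopifnot(inherits(burst, "eit_burst"))
  if (!is.null(burst$n_discard) && burst$n_discard > 0)
    stop("remove the discard prefix with trim_burst() before demodulating", call. = FALSE)
  n <- length(burst$samples)
  if (n == 0) stop("empty burst", call. = FALSE)
  if (n / burst$sample_rate < 1 / frequency - 1e-12)
    stop("burst must cover at least one full signal cycle", call. = FALSE)
  cycles <- frequency * n / burst$sample_rate
  if (abs(cycles - round(cycles)) > 1e-9)
    warning("burst does not cover an integer number of cycles; demodulation is subject to spectral leakage")
  theta <- burst$phase_reference + 2 * pi * frequency * (0:(n - 1)) / burst$sample_rate
  i <- 2 / n * sum(burst$samples * sin(theta))
  q <- 2 / n * sum(burst$samples * cos(theta))
  phi <- atan2(q, i)
  if (phi <= -pi) phi <- phi + 2 * pi
  structure(list(in_phase = i, quadrature = q,
                 magnitude = sqrt(i^2 + q^2), phase = phi),
            class = "iq_demod")
}

#' Check a sampling configuration for demodulation coherence
#'
#' Demodulation is exact (no spectral leakage) when the total sampling time
#' is an integer multiple of both the sample period and the signal period.
#' For non-coherent configurations the worst-case magnitude bias of a unit
#' sinusoid is estimated by a numeric sweep over signal phase.
#'
#' @param x An [excitation_spec()] (sample rate and record length derived
#'   from it), or the signal frequency in Hz.
#' @param sample_rate Sampling rate in Hz (required when `x` is a
#'   frequency).
#' @param n_samples Record length in samples (required when `x` is a
#'   frequency).
#' @param n_phase Phase grid size for the leakage sweep.
#' @return List with `coherent` (logical) and `leakage` (worst-case
#'   absolute magnitude bias for a unit-amplitude signal; 0 when coherent).
#' @examples
#' coherence_check(excitation_spec())$coherent            # TRUE
#' coherence_check(25000, 260000, 100)$coherent           # FALSE
#' @export
coherence_check <- function(x, sample_rate = NULL, n_samples = NULL,
                            n_phase = 64L) {
  if (inherits(x, "excitation_spec")) {
    frequency <- x$frequency
    sample_rate <- x$frequency * x$samples_per_cycle
    n_samples <- x$n_cycles * x$samples_per_cycle
  } else {
    frequency <- x
    if (is.null(sample_rate) || is.null(n_samples))
      stop("supply sample_rate and n_samples with a raw frequency", call. = FALSE)
  }
  cycles <- frequency * n_samples / sample_rate
  coherent <- abs(cycles - round(cycles)) < 1e-9
  if (coherent) return(list(coherent = TRUE, leakage = 0))
  phases <- seq(0, 2 * pi, length.out = n_phase + 1L)[-(n_phase + 1L)]
  t <- (0:(n_samples - 1)) / sample_rate
  theta <- 2 * pi * frequency * t
  bias <- vapply(phases, function(ph) {
    s <- sin(theta + ph)
    i <- 2 / n_samples * sum(s * sin(theta))
    q <- 2 / n_samples * sum(s * cos(theta))
    abs(sqrt(i^2 + q^2) - 1)
  }, numeric(1))
  list(coherent = FALSE, leakage = max(bias))
}
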