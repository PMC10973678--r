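#' Single-stage instrumentation amplifier gain
#'
#' The measurement amplifiers are AD8220-class instrumentation amplifiers
#' whose gain is set by an external resistance: G = 1 + 49400 / RG.
#'
#' @param r_gain Gain-setting resistance in ohms (> 0; `Inf` gives the
#'   unity-gain limit).
#' @param gain_constant Internal gain constant in ohms (49400 for the
#'   AD8220).
#' @return Dimensionless voltage gain.
#' @examples
#' stage_gain(49400)  # 2
#' @export
stage_gain <- function(r_gain, gain_constant = 49400) {
  if (any(!is.na(r_gain) & r_gain <= 0))
    stop("r_gain must be positive", call. = FALSE)
  1 + gain_constant / r_gain
}

#' Two-stage amplifier chain description
#'
#' Each stage's gain resistance is a digital potentiometer (AD5262-class:
#' 256 uniform positions over `pot_max`, in series with a wiper
#' resistance), so per-stage resistance ranges over
#' `[wiper, wiper + pot_max]`.
#'
#' @param gain_constant Amplifier gain constant in ohms.
#' @param pot_max Potentiometer full-scale resistance in ohms.
#' @param wiper Wiper resistance in ohms.
#' @param pot_steps Discrete potentiometer positions per stage.
#' @return An object of class `amplifier_chain`.
#' @export
amplifier_chain <- function(gain_constant = 49400, pot_max = 50000,
                            wiper = 150, pot_steps = 256L) {
  stopifnot(pot_max > 0, wiper >= 0, pot_steps >= 2)
  structure(list(gain_constant = gain_constant, pot_max = pot_max,
                 wiper = wiper, pot_steps = as.integer(pot_steps)),
            class = "amplifier_chain")
}

#' Total gain range of the two-stage amplifier
#'
#' The minimum total gain occurs with both potentiometers at full
#' resistance (wiper + pot_max per stage), the maximum with both at the
#' bare wiper resistance. Total gain is the product of the two stage gains.
#'
#' @param chain An [amplifier_chain()].
#' @return Named numeric vector `c(min_gain, max_gain)`.
#' @examples
#' total_gain_bounds(amplifier_chain())  # ~3.95 (reported as 4) to ~1.1e5
#' @export
total_gain_bounds <- function(chain = amplifier_chain()) {
  stopifnot(inherits(chain, "amplifier_chain"))
  g_min <- stage_gain(chain$wiper + chain$pot_max, chain$gain_constant)^2
  g_max <- stage_gain(max(chain$wiper, .Machine$double.eps), chain$gain_constant)^2
  c(min_gain = g_min, max_gain = g_max)
}

#' Voltage-controlled current source (Howland pump) model
#'
#' The drive chain is: signal source (0.21 V RMS) -> non-inverting
#' preamplifier (gain 3.4) -> modified Howland pump with a matched resistor
#' grid (gain 1), whose output current is the drive voltage divided by the
#' R5 digital potentiometer. By default the drive voltage is carried at the
#' device firmware's rounded value (0.21 x 3.4 = 0.714, rounded to 0.72 V),
#' reproducing the rated 98 uA output with R5 = 7347 ohm; set
#' `round_drive = FALSE` for full precision.
#'
#' @param r5 Current-setting resistance in ohms (> 0).
#' @param input_rms Source RMS voltage.
#' @param preamp_gain Preamplifier gain.
#' @param howland_gain Howland gain (1 for a matched grid).
#' @param round_drive Use the firmware's documented drive constant
#'   (`nominal_drive`, 0.72 V) instead of the exact product
#'   `input_rms * preamp_gain` (0.714 V)?
#' @param nominal_drive The documented drive voltage in volts.
#' @return An object of class `current_source_model`.
#' @export
current_source_model <- function(r5, input_rms = 0.21, preamp_gain = 3.4,
                                 howland_gain = 1, round_drive = TRUE,
                                 nominal_drive = 0.72) {
  if (!is.numeric(r5) || any(r5 <= 0))
    stop("r5 must be positive", call. = FALSE)
  structure(list(r5 = r5, input_rms = input_rms, preamp_gain = preamp_gain,
                 howland_gain = howland_gain, round_drive = isTRUE(round_drive),
                 nominal_drive = nominal_drive),
            class = "current_source_model")
}

#' RMS output current of the VCCS
#'
#' @param model A [current_source_model()].
#' @return Output current in amperes RMS.
#' @examples
#' vccs_output_current(current_source_model(r5 = 7347))  # ~98 uA, the rated output
#' @export
vccs_output_current <- function(model) {
  stopifnot(inherits(model, "current_source_model"))
  drive <- if (model$round_drive) model$nominal_drive
           else model$input_rms * model$preamp_gain
  model$howland_gain * drive / model$r5
}

#' Patient-current safety model (IEC 60601 type BF limits)
#'
#' Series capacitors block all DC paths, so DC patient current is zero in
#' both normal and single-fault conditions. Under a single fault the worst
#' case AC waveform is a square wave swinging across the supply rails; its
#' RMS value is half the peak-to-peak swing, and a series safety resistance
#' holds the resulting current below the 500 uA single-fault limit.
#'
#' @param v_peak_to_peak Supply swing in volts (6.6 V).
#' @param r_safety Series safety resistance in ohms (5.6 kohm + 1 kohm).
#' @param ac_limit_normal,ac_limit_fault,dc_limit_normal,dc_limit_fault
#'   Allowed patient auxiliary currents in amperes.
#' @return An object of class `safety_model`.
#' @export
safety_model <- function(v_peak_to_peak = 6.6, r_safety = 5600 + 1000,
                         ac_limit_normal = 100e-6, ac_limit_fault = 500e-6,
                         dc_limit_normal = 10e-6, dc_limit_fault = 50e-6) {
  stopifnot(r_safety > 0, v_peak_to_peak >= 0)
  structure(list(v_peak_to_peak = v_peak_to_peak, r_safety = r_safety,
                 ac_limit_normal = ac_limit_normal, ac_limit_fault = ac_limit_fault,
                 dc_limit_normal = dc_limit_normal, dc_limit_fault = dc_limit_fault),
            class = "safety_model")
}

#' Single-fault AC current and limit check
#'
#' @param model A [safety_model()].
#' @return List with `v_rms` (fault-condition RMS voltage, half the
#'   peak-to-peak square swing), `current` (amperes RMS), `limit` and
#'   `passes` (does the fault current stay at or below the single-fault
#'   limit?).
#' @examples
#' fault_current(safety_model(6.6, 6600))$current  # exactly 500 uA
#' @export
fault_current <- function(model = safety_model()) {
  stopifnot(inherits(model, "safety_model"))
  v_rms <- 0.5 * model$v_peak_to_peak
  i <- v_rms / model$r_safety
  list(v_rms = v_rms, current = i, limit = model$ac_limit_fault,
       passes = i <= model$ac_limit_fault)
}

#' Check an operating current against the safety limits
#'
#' @param current Current in amperes RMS.
#' @param model A [safety_model()].
#' @param condition `"normal"` or `"fault"`.
#' @param type `"ac"` or `"dc"`.
#' @return List with `current`, `limit`, `passes`.
#' @examples
#' safety_check(98e-6)$passes  # rated output passes the 100 uA normal limit
#' @export
safety_check <- function(current, model = safety_model(),
                         condition = c("normal", "fault"), type = c("ac", "dc")) {
  condition <- match.arg(condition)
  type <- match.arg(type)
  limit <- model[[paste0(type, "_limit_", condition)]]
  list(current = current, limit = limit, passes = current <= limit)
}

#' ADC model
#'
#' @param full_scale Full-scale input voltage.
#' @param effective_bits Effective resolution in bits (13 for the device's
#'   16-bit converter under normal noise conditions).
#' @return An object of class `adc_model` with the least significant bit
#'   voltage precomputed.
#' @export
adc_model <- function(full_scale = 3.3, effective_bits = 13L) {
  stopifnot(full_scale > 0, effective_bits >= 1)
  lsb <- full_scale / 2^effective_bits
  structure(list(full_scale = full_scale, effective_bits = as.integer(effective_bits),
                 lsb = lsb), class = "adc_model")
}

#' Quantize voltages through the ADC model
#'
#' Rounds to the nearest LSB and clips to the full-scale range, so any
#' in-range voltage is reproduced to within lsb/2.
#'
#' @param adc An [adc_model()].
#' @param v Voltages.
#' @return Quantized voltages.
#' @export
adc_quantize <- function(adc, v) {
  stopifnot(inherits(adc, "adc_model"))
  q <- round(v / adc$lsb) * adc$lsb
  pmin(pmax(q, -adc$full_scale), adc$full_scale)
}

#' Quantization resolution summary
#'
#' @param adc An [adc_model()].
#' @param min_channel_peak Smallest channel amplitude of interest, in volts
#'   (must lie in (0, full_scale]).
#' @return List with `lsb` (volts) and `relative_error` (lsb divided by the
#'   minimum channel peak).
#' @examples
#' s <- quantization_summary(adc_model(3.3, 13), 0.19)
#' s$lsb * 1e3           # ~0.4 mV
#' s$relative_error * 100  # ~0.2 %
#' @export
quantization_summary <- function(adc, min_channel_peak) {
  stopifnot(inherits(adc, "adc_model"))
  if (!is.numeric(min_channel_peak) || min_channel_peak <= 0 ||
      min_channel_peak > adc$full_scale)
    stop("min_channel_peak must lie in (0, full_scale]", call. = FALSE)
  list(lsb = adc$lsb, relative_error = adc$lsb / min_channel_peak)
}

#' One-shot device report
#'
#' Summarizes the analytic electronics model: gain range, rated output
#' current, safety margins and ADC resolution.
#'
#' @param chain An [amplifier_chain()].
#' @param source A [current_source_model()].
#' @param safety A [safety_model()].
#' @param adc An [adc_model()].
#' @param min_channel_peak Smallest channel amplitude for the quantization
#'   summary.
#' @return A nested list (convertible to JSON).
#' @export
device_report <- function(chain = amplifier_chain(),
                          source = current_source_model(r5 = 7347),
                          safety = safety_model(),
                          adc = adc_model(),
                          min_channel_peak = 0.19) {
  bounds <- total_gain_bounds(chain)
  i_out <- vccs_output_current(source)
  fault <- fault_current(safety)
  q <- quantization_summary(adc, min_channel_peak)
  list(
    gain = list(min_total = unname(bounds["min_gain"]),
                max_total = unname(bounds["max_gain"])),
    current = list(output_rms_uA = i_out * 1e6,
                   normal_limit_uA = safety$ac_limit_normal * 1e6,
                   normal_passes = safety_check(i_out, safety)$passes),
    single_fault = list(current_uA = fault$current * 1e6,
                        limit_uA = fault$limit * 1e6, passes = fault$passes),
    adc = list(lsb_mV = q$lsb * 1e3,
               relative_error_pct = q$relative_error * 100)
  )
}
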