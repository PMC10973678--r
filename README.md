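# eittwin

A software twin of a low-cost wearable **electrical impedance tomography
(EIT)** device and of the salt-bath bench used to characterize it. EIT
drives a small alternating current through one pair of boundary
electrodes while measuring voltages across other pairs, sweeps all such
four-electrode combinations (one *frame*), and inverts the pattern into
an image of the conductivity change inside the domain.

The package is aimed at EIT hardware and algorithm developers who want a
faithful, fully synthetic stand-in for a physical device: it generates
drive/measure protocols, models the analogue electronics analytically,
synthesizes and I/Q-demodulates the sampled signals, speaks the device's
ASCII serial frame format, implements ISO 11095-style calibration with
inverse prediction, solves the 2-D forward problem on a circular bath,
reconstructs time-difference images, and evaluates the full EIT
performance-measure suite — with a deterministic phantom generator
supplying every input.

## The core models

**Excitation matrix.** With `n` electrodes, drive spacing `d` and
measurement step `s`, each electrode serves once as drive+ (drive− is
`d` above it); measure− walks from one past drive− around the ring, with
measure+ `s` above it, skipping any pair that touches a drive electrode.
At the device defaults (16, 3, 1) this yields 16 x 12 = **192**
measurements per frame.

**Reconstruction.** One-step Tikhonov-regularized time difference:

    x̂ = (JᵀJ + λR)⁻¹ Jᵀ y,   R = diag(JᵀJ)ᵖ,   λ = 0.05, p = 0.5

where `J` is the FEM sensitivity (Jacobian) matrix at the background
conductivity and `y` the difference between target and background
frames. Images are rasterized to a 64 x 64 grid for the pixel measures
(detectability, distinguishability, and the GREIT figures of merit:
amplitude, position error, resolution, ringing).

**Calibration.** `y_nk = β₀ + β₁ x_n + ε_nk` fitted over repeated
indications at reference set points, 95 % uncertainty `2σ̂`, inverse
prediction `x* = (ȳ − β̂₀)/β̂₁`; a proportional-variance variant fitted
via `y/x ~ 1/x`, and a three-stage voltage-chain composition with
discrete two-potentiometer gain planning.

## Worked example

```r
library(eittwin)

build_protocol(eit_protocol_config(16, 3, 1))
#> EIT measurement protocol: 192 measurements (16 electrodes, dist_exc = 3, step_meas = 1)
#>   v_plus v_minus m_plus m_minus
#> 1      1       4      6       5
#> 2      1       4      7       6
#> ...
```

192 quadruples per frame; the first injection drives electrodes (1, 4)
and measures (6, 5) upward around the ring.

```r
str(device_report(), digits.d = 4)
#> $ gain        : min_total: 3.94,  max_total: 109120
#> $ current     : output_rms_uA: 98,  normal_limit_uA: 100, normal_passes: TRUE
#> $ single_fault: current_uA: 500,  limit_uA: 500,  passes: TRUE
#> $ adc         : lsb_mV: 0.4028,  relative_error_pct: 0.212
```

The analytic electronics model reproduces the device's headline numbers:
two-stage gain from ~4 to ~1.1e5, rated 98 µA output inside the 100 µA
IEC 60601 normal-condition limit, exactly 500 µA under the single-fault
worst case, and a 0.4 mV ADC step (0.2 % of the smallest channel).

```r
st <- single_target_study(seed = 1)
st$per_position[, c("position", "detectability_frames", "resolution", "ringing")]
#>   position detectability_frames resolution ringing
#> 1      -80                 49.8      0.356  0.1068
#> 2      -60                 49.1      0.415  0.0929
#> 3      -40                 47.1      0.431  0.0782
#> 4      -20                 45.0      0.437  0.0840
#> 5        0                 44.5      0.442  0.0821
#> 6       20                 44.6      0.437  0.0836
#> 7       40                 46.5      0.431  0.0859
#> 8       60                 47.7      0.415  0.1015
#> 9       80                 50.1      0.354  0.1106
range(st$snr_db)   # 37.2 .. 61.2 dB channel SNR
min(st$accuracy)   # 0.994
```

This emulates the 9-position bench sweep of a 50 mm insulating target:
noise-referenced detectability rises from 44.5 dB at the centre to
~50 dB at ±80 mm (boundary targets produce more signal), resolution
falls, ringing grows, and the ± sides mirror each other. The
two-target study behaves the same way for separation:

```r
two_target_study(seed = 1)$per_separation
#>   separation distinguishability distinguishability_frames
#> 1         40              8.826                     24.07
#> 2         60              8.440                     30.72
#> 3         80              9.002                     35.51
#> 4        100              8.570                     39.13
```

Distinguishability (against the one object of the same combined area)
climbs 24 → 39 dB as the pair separates.

A thin command-line wrapper over the same functions lives in
`inst/scripts/eit-tools.R` (`protocol`, `parse`, `demod`, `report`
subcommands).

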