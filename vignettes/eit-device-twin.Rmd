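---
title: "A software twin of a wearable EIT system: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A software twin of a wearable EIT system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eittwin)
```

## What this package models

Electrical impedance tomography (EIT) maps the conductivity distribution
inside a domain from boundary measurements: a small alternating current is
driven through one pair of electrodes while the potential difference is
measured across other pairs, and the pattern of such four-electrode
measurements is inverted into an image. `eittwin` is a software twin of a
low-cost wearable EIT device and of the salt-bath bench on which such
devices are characterized. It covers the whole chain:

1. **Protocol** — the excitation matrix: the ordered drive/measure
   electrode quadruples of one frame.
2. **Device model** — analytic electronics: instrumentation-amplifier
   gains, the Howland voltage-controlled current source, IEC 60601 patient
   current limits, ADC quantization.
3. **Signal** — DAC staircase synthesis, burst sampling with a switching
   transient, and I/Q demodulation.
4. **Codec** — the device's ASCII serial frame format.
5. **Calibration** — ISO 11095-style linear calibration with inverse
   prediction, a proportional-variance variant, and the three-stage
   voltage-chain composition with discrete gain planning.
6. **Forward model** — 2-D finite elements on a disk, with the sensitivity
   (Jacobian) matrix.
7. **Reconstruction** — one-step Tikhonov-regularized time-difference
   imaging and rasterization.
8. **Metrics** — channel SNR, accuracy, Allan deviation, drift,
   detectability, distinguishability, and the GREIT figures of merit.
9. **Phantom** — a deterministic synthetic-data generator emulating the
   salt-bath experiment, which supplies every test input.

## The drive/measure protocol

Electrodes are numbered 1..n counterclockwise. Each electrode serves once
as drive+, with drive− `dist_exc` positions above it (wrapping). For each
injection, measure− starts one past drive− and walks the ring until it
returns to drive−, with measure+ `step_meas` positions above measure−.
Any candidate pair that touches either drive electrode is skipped — a
measurement across a current-carrying electrode is not a four-terminal
measurement. At the device defaults (n = 16, `dist_exc` = 3,
`step_meas` = 1) each of the 16 injections keeps 12 pairs: 192
measurements per frame. For `dist_exc = 1` two of the four exclusion
slots coincide, so each injection keeps `n − 3` pairs rather than
`n − 4`; `count_measurements()` always counts by enumeration, so these
edge configurations are handled exactly.

## Electronics as algebra, not circuits

The electronics module is deliberately analytic. Each amplifier stage has
gain `1 + 49400 / RG` with `RG` a 256-step digital potentiometer (wiper
150 ohm, full scale 50 kohm), giving a two-stage range from about 3.94
("4") to about 1.09e5. The current source is modelled by its transfer
constant: a 0.21 V RMS source, a preamplifier of gain 3.4, and a matched
Howland stage deliver `0.72 V / R5` amperes; the firmware's documented
drive constant 0.72 V (the exact product is 0.714 V) is the default so
the rated 98 uA at R5 = 7347 ohm is reproduced, with `round_drive =
FALSE` for full precision. Patient safety uses the worst-case analysis:
series capacitors zero all DC paths, and under a single fault the output
swings rail-to-rail (6.6 V peak-to-peak, RMS half that for a square
wave), which the 6.6 kohm series safety resistance holds to exactly
500 uA — the IEC 60601 single-fault limit. The ADC is a 3.3 V, 13
effective-bit quantizer (LSB 0.4 mV, 0.2 % of the smallest 0.19 V
channel). Op-amp bandwidth, offsets and output impedance are out of
scope.

## Burst sampling and I/Q demodulation

Each measurement samples the amplified sinusoid 10 times per 25 kHz cycle
over up to 10 cycles, after discarding 10 samples (40 us) to clear the
roughly 30 us multiplexer switching transient; the twin models that
transient as an exponential settling with a 10 us time constant — only
its extent matters, and tests assert discard sufficiency rather than its
shape. Demodulation multiplies the record by in-phase and quadrature
references and averages (the firmware uses a plain mean as its low-pass
filter). The `2/N` scaling makes the reported magnitude equal the
sinusoid's peak amplitude, directly comparable to applied voltages; the
phase reference is the synthesized excitation's phase at the first
retained sample. Recovery is exact whenever the record spans an integer
number of signal cycles (coherent sampling); `coherence_check()`
quantifies the worst-case leakage bias otherwise by a numeric sweep over
phase.

## Calibration

The current source and the voltage chain are calibrated against repeated
measurements at reference set points. The constant-variance model `y =
b0 + b1 x + e` is fitted by ordinary least squares over all repetitions,
with the residual SD on `n − 2` pooled degrees of freedom and the 95 %
uncertainty reported as `2 * sigma_hat` — the device's convention, which
is why a 0.1381 uA residual SD prints as +/- 0.28 uA (a t-quantile would
differ in the third digit at 48 degrees of freedom). When the residual
dispersion grows with the fitted value (which `check_constant_variance()`
flags by correlating absolute residuals with fitted values), the
proportional-variance model is fitted instead by regressing `y/x` on
`1/x`; the transformed intercept and slope swap roles. Inverse
prediction `(target − intercept) / slope` turns either fit into a
set-point calculator.

The voltage chain is calibrated in three stages (input to first
amplifier, first to second, second to the reported voltage), each stage's
indication being the externally measured output divided by the nominal
stage gain. The composition into a single affine model is exact algebra,
and the combined model doubles as a gain planner: an exhaustive search
over the 256 x 256 potentiometer code grid picks the pair of stage gains
whose predicted reported voltage is closest to a target without clipping,
tie-broken toward lower total gain. The device policy targets 90 % of the
ADC full scale for the largest channel.

## Forward model and Jacobian

The bath is a 240 mm acrylic disk filled to 10 mm with saline of 0.194
ohm-m resistivity; the twin treats it as a 2-D sheet (conductivities are
effective sheet values — absolute scale is irrelevant for difference
imaging). The mesh is a deterministic structured triangulation:
`2 * refinement` concentric rings, ring i carrying `16 i` nodes, giving
1024 well-shaped, nearly uniform elements at the default refinement 4 and
electrodes landing exactly on boundary nodes. Electrodes are points
(the 4.6 mm electrodes are small against the 240 mm bath; no contact
impedance), currents are injected as nodal sources, and the linear FEM
system is solved with one sparse factorization per conductivity field.
Against the closed-form two-boundary-point-source solution on a disk, the
default mesh is within 2 % on all 192 channels, converging with
refinement. The Jacobian uses the adjoint identity — minus the integral
of the dot product of drive and measurement field gradients over each
element — and is sign-adjusted to differentiate the device's magnitude
(absolute value) measurements; a finite-difference sweep on a coarse mesh
agrees to better than 1e-3 relative.

## Reconstruction

Time-difference images solve `(JtJ + lambda R) x = Jt y` with `R =
diag(diag(JtJ))^p`, one linear step, `lambda = 0.05`, `p = 0.5` (the
device stack's heuristics: lambda for shape and ringing, p as a
compromise between pushing noise to the boundary or the centre). These
hyperparameters are meaningful on the dimensionless unit problem the
device software works in, so the Jacobian is internally rescaled by
`sigma_ref^2 / current` before inversion; in physical units (98 uA,
S/m) the same lambda would over-regularize by six orders of magnitude.
The difference vector is the plain difference of channel magnitudes by
default, with a normalized mode (`(vt − vb)/vb`) available. Images are
sign-flipped so insulating (acrylic) targets appear positive, and are
rasterized to a 64 x 64 grid (each in-disk pixel takes its containing
element's value) for the pixel-based measures.

## The phantom generator: what it emulates, and what it does not

`standard_single_target_session()` reproduces the single-target bench: a
50 mm insulating disk at 9 positions 20 mm apart along one diameter
(-80 to 80 mm; the placement axis is one diameter, matching the +/-
radial labelling of the bench results), 20 frames per position at 2
frames/s, plus 20 empty-bath frames. `standard_two_target_session()`
places two 35.36 mm disks (half the area each, combined area equal to
the 50 mm target) at centre-to-centre separations 40 to 100 mm in 20 mm
steps — the first just beyond touching — and includes the 50 mm
centre target as the reference object, since distinguishability asks how
well two targets are told apart from one object of the same combined
area. `standard_drift_session()` is a 2 h empty-bath run at 1 frame/s
for Allan deviation and drift.

Targets are painted onto the mesh by area fraction: each element's
conductivity is the partial-volume mixture of background and target
according to the fraction of its area inside the circle (barycentric
quadrature). A centre-in-target rule is available but not the default:
with a structured mesh its painted area can err by tens of percent when
a target circle grazes a ring of element centroids (43 % for the centred
50 mm target), which distorts the radial trends; the fraction rule stays
within about 1 %. Insulating acrylic is modelled as a conductivity ratio
of 1e-6, keeping the system well posed.

Noise is multiplicative per channel: each channel draws a true SNR
uniformly from the device band (36-63 dB) narrowed by a 3 dB guard on
each side, so that SNR *estimated* from 20 frames still falls inside the
nominal band, and Gaussian noise of SD `mean / 10^(SNR/20)` is added.
Drift is a shared multiplicative random walk with a per-frame step of
7.4e-5, chosen so the expected absolute drift over 30 min at 1 frame/s
is about 0.25 %, the device's reported figure. A session-wide gain
scales the largest background channel to 90 % of the 3.3 V ADC full
scale (the device's gain-tuning policy), which puts magnitudes in the
reported 0.19-1.5 V range and makes the 4-decimal serial format
meaningful. The generator is deterministic under its seed.

What the generator does *not* emulate: electrode contact impedance and
electrochemistry, solution movement after target placement (the bench
waits 30 s), temperature dependence, correlated or non-Gaussian noise,
ADC quantization of the frame stream, and any systematic forward-model
error — the twin's forward model is also the reconstruction model. Tests
passing on these sessions therefore validate the pipeline's internal
consistency and its statistical behaviour under the device's noise
levels, not robustness to the modelling errors a physical bench adds.

## Performance measures and the two detectability readings

Channel SNR is `20 log10(mean/SD)` per channel across frames; accuracy
min-max normalizes measured and simulated channel means to [0, 1] and
reports one minus their absolute difference (hence invariance to affine
distortions of either vector); the Allan deviation uses non-overlapping
bins; drift compares windowed means a span apart. The ROI of an image is
the set of pixels above a quarter of the maximum. The GREIT figures of
merit compare a measured reconstruction with the noiseless simulated
reconstruction of the same configuration: amplitude (mean of in-disk
pixels; an ROI-only switch exists), position error (difference of the
two ROI-weighted centre-of-mass distances from the bath centre),
resolution (square root of ROI area over disk area), and ringing
(magnitude of negative pixels outside the ROI over positive pixels
inside it). Sample SDs use the n−1 convention throughout.

Detectability is reported in two readings. The literal one — mean over
SD of the ROI pixels of one image, in dB — is what `detectability()`
computes. In this twin it saturates near the shape statistic of the
point-spread function (about 8.5 dB) because channel noise is small
after 20-frame averaging, and it is not monotone in target position. The
noise-referenced reading exploits the linearity of the reconstruction:
the ROI-mean image value is a linear functional of the measurement
frame, so its signal (applied to the mean difference vector) and its
frame-to-frame noise SD (propagated from per-channel sample variances,
with far more effective degrees of freedom than the 20-sample SD of the
scalar itself) give a signal-to-noise ratio in dB. That reading rises
monotonically with the target's radial position — boundary targets
produce more signal — and with two-target separation, reproducing the
device's reported trends; the studies report both columns.
Distinguishability is the same statistic computed against the
single-object reference instead of the empty bath.

## Numerical choices and degenerate inputs

Zero-noise calibration fits are legitimate and return exact coefficients
(residual trend statistics are forced to zero below numerical noise).
Constant channels and uniform ROIs return an infinite-SNR sentinel
rather than an error. The forward solver grounds the centre node and
works with potential differences, so the gauge never enters
measurements. The gain planner breaks ties toward the lower total gain
and reports the closest achievable setting with a flag when the target
is infeasible. Frame decoding tolerates the header with or without its
leading CRLF and one- or two-character separators (the printed format's
character counts are internally inconsistent by one), emits the literal
printed dialect, and flags malformed tokens per frame instead of
aborting. Problem sizes were chosen for interactive use: the default
mesh (1024 elements) solves a frame in about 20 ms, a full Jacobian in
under a second, and both bench studies in a few seconds.

## Known limitations

The point-electrode, 2-D, no-contact-impedance forward model limits
realism near electrodes; the twin cannot reproduce device-specific
hardware results (those depend on the physical bench), only the analytic
values and the statistical/qualitative behaviour above. Within-image
detectability is reported for completeness but is uninformative at this
noise level. Multi-frequency EIT, absolute imaging, iterative
Gauss-Newton, GREIT-matrix training, and mesh auto-tuning are out of
scope.
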