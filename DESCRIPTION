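Package: eittwin
Title: Software Twin of a Wearable Electrical Impedance Tomography System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A software twin of a low-cost wearable electrical impedance
    tomography (EIT) device and its bench characterization. Builds and
    validates four-electrode drive/measure protocols (excitation matrices),
    models the analogue electronics chain (instrumentation-amplifier gains,
    Howland current source, IEC 60601 safety currents, ADC quantization),
    synthesizes and I/Q-demodulates burst-sampled excitation signals,
    reads and writes the device's ASCII measurement-frame stream,
    implements ISO 11095-style linear calibration with inverse prediction
    and multi-stage gain-chain composition, solves the 2-D finite-element
    forward problem on a circular salt-bath phantom, reconstructs
    time-difference conductivity images with Tikhonov-regularized one-step
    inversion, and evaluates the full suite of EIT performance measures
    (channel SNR, accuracy, Allan deviation, drift, detectability,
    distinguishability, and the GREIT figures of merit). A synthetic
    phantom module generates all test data, emulating a 240 mm salt-bath
    experiment with insulating acrylic targets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
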