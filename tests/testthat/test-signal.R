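test_that("synthesized staircase has the specified levels, span and zero mean", {
  spec <- excitation_spec()
  w <- synth_excitation(spec, duration = 1 / spec$frequency)
  expect_equal(length(unique(w$value)), 16L)         # all levels distinct
  expect_equal(max(w$value) - min(w$value), 0.6)     # peak-to-peak span
  expect_equal(mean(w$value), 0, tolerance = 1e-12)
  # converges to an ideal sine: RMS -> pp / (2 sqrt 2) = 0.2121 (0.21 reported)
  fine <- synth_excitation(excitation_spec(dac_levels = 4096),
                           duration = 1 / spec$frequency)
  expect_equal(sqrt(mean(fine$value^2)), 0.6 / (2 * sqrt(2)), tolerance = 1e-4)
  expect_equal(unique(synth_excitation(excitation_spec(amplitude_pp = 0))$value), 0)
  expect_error(synth_excitation(spec, duration = 1e-6), "cycle")
})

test_that("discard interval covers the switching transient at the device defaults", {
  spec <- excitation_spec()
  # 10 samples at 250 kHz = 40 us guard for the ~30 us transient
  expect_equal(spec$discard_samples / (spec$frequency * spec$samples_per_cycle),
               40e-6)
  b <- simulate_burst(spec, amplitude = 1, transient_tau = 10e-6)
  expect_equal(b$n_discard, 10L)
  expect_equal(length(b$samples), 10L + 10L * 10L)
  # magnitude is invariant to the discarded transient once trimmed
  clean <- simulate_burst(spec, amplitude = 1, transient_amplitude = 0)
  m_t <- iq_demodulate(trim_burst(b))$magnitude
  m_c <- iq_demodulate(trim_burst(clean))$magnitude
  expect_equal(m_t, m_c, tolerance = 1e-3)  # residual transient < exp(-4)
  expect_equal(m_c, 1, tolerance = 1e-12)
})

test_that("coherent demodulation recovers amplitude and phase exactly across an (A, phi) sweep", {
  spec <- excitation_spec()
  for (a in seq(0.1, 3.3, length.out = 10)) {
    for (phi in seq(-3, 3, length.out = 10)) {
      b <- trim_burst(simulate_burst(spec, amplitude = a, phase = phi,
                                     transient_amplitude = 0))
      d <- iq_demodulate(b)
      expect_equal(d$magnitude, a, tolerance = 1e-10)
      expect_equal(d$phase, phi, tolerance = 1e-9)
      expect_true(d$phase > -pi && d$phase <= pi)
      expect_equal(d$magnitude, sqrt(d$in_phase^2 + d$quadrature^2))
    }
  }
})

test_that("known demodulation identities hold", {
  spec <- excitation_spec()
  d <- iq_demodulate(trim_burst(simulate_burst(spec, 0.5, phase = pi / 6,
                                               transient_amplitude = 0)))
  expect_equal(d$magnitude, 0.5, tolerance = 1e-12)
  expect_equal(d$phase, pi / 6, tolerance = 1e-12)
  # DC input over integer cycles demodulates to zero
  b <- trim_burst(simulate_burst(spec, 0, transient_amplitude = 0))
  b$samples <- rep(0.7, length(b$samples))
  expect_equal(iq_demodulate(b)$magnitude, 0, tolerance = 1e-12)
  expect_error(iq_demodulate(structure(list(samples = numeric(0),
                                            sample_rate = 2.5e5, n_discard = 0L,
                                            phase_reference = 0, frequency = 2.5e4),
                                       class = "eit_burst")), "empty")
})

test_that("noisy bursts demodulate to the true amplitude within Monte-Carlo error", {
  spec <- excitation_spec()
  set.seed(421)
  reps <- 300
  m <- replicate(reps, iq_demodulate(trim_burst(
    simulate_burst(spec, 1.0, noise_sd = 0.01, transient_amplitude = 0)))$magnitude)
  # I,Q noise sd = noise_sd * sqrt(2/N); magnitude nearly unbiased at A >> sd
  se <- 0.01 * sqrt(2 / 100) / sqrt(reps)
  expect_lt(abs(mean(m) - 1.0), 4 * se)
})

test_that("quantization-induced magnitude error stays below one LSB for coherent bursts", {
  spec <- excitation_spec()
  adc <- adc_model(3.3, 13)
  for (a in seq(0.19, 3.2, length.out = 12)) {
    b <- trim_burst(simulate_burst(spec, a, transient_amplitude = 0, adc = adc))
    expect_lt(abs(iq_demodulate(b)$magnitude - a), adc$lsb)
  }
})

test_that("coherence check separates coherent from leaky configurations", {
  expect_true(coherence_check(excitation_spec())$coherent)
  expect_equal(coherence_check(excitation_spec())$leakage, 0)
  expect_true(coherence_check(excitation_spec(n_cycles = 1))$coherent)
  nc <- coherence_check(25000, 260000, 100)
  expect_false(nc$coherent)
  expect_gt(nc$leakage, 0)
  # the leakage estimate bounds the observed bias for that configuration
  t <- (0:99) / 260000
  theta <- 2 * pi * 25000 * t
  worst <- max(vapply(seq(0, 2 * pi, length.out = 200), function(ph) {
    s <- sin(theta + ph)
    abs(sqrt((2 / 100 * sum(s * sin(theta)))^2 +
               (2 / 100 * sum(s * cos(theta)))^2) - 1)
  }, numeric(1)))
  expect_gte(nc$leakage * 1.02, worst * 0.98)
})

test_that("clipping is flagged but not fatal", {
  spec <- excitation_spec()
  adc <- adc_model(3.3, 13)
  b <- simulate_burst(spec, amplitude = 3.3, phase = 0, adc = adc,
                      transient_amplitude = 3.3)
  expect_true(b$clipped)
  expect_true(all(abs(b$samples) <= adc$full_scale))
})
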