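test_that("channel SNR matches the dB definition and converges to the population value", {
  set.seed(31)
  # constant channel -> infinite SNR sentinel
  frames <- cbind(rep(1, 10), rnorm(10, 100, 1))
  expect_equal(channel_snr(frames)[1], Inf)
  # mu/sigma = 100 -> 40 dB; channel-averaged estimate is tight at 20 frames
  f20 <- matrix(rnorm(20 * 192, 100, 1), nrow = 20)
  expect_lt(abs(mean(channel_snr(f20)) - 40), 1)
  f4k <- matrix(rnorm(4000 * 64, 100, 1), nrow = 4000)
  expect_lt(abs(mean(channel_snr(f4k)) - 40), 0.1)
  expect_error(channel_series(matrix(1, 1, 3)), "2 frames")
})

test_that("accuracy is 1 on self-comparison and invariant to affine rescaling", {
  set.seed(32)
  v <- runif(192, 0.19, 1.5)
  expect_equal(channel_accuracy(v, v), rep(1, 192))
  expect_equal(channel_accuracy(3.7 * v - 0.2, v), rep(1, 192))
  expect_equal(channel_accuracy(v, 0.01 * v + 5), rep(1, 192))
  # definitional: a channel off by 0.09 after normalization scores 0.91
  a <- c(0, 0.5, 1)
  b <- c(0, 0.59, 1)
  expect_equal(channel_accuracy(b, a)[2], 0.91)
  expect_error(channel_accuracy(rep(1, 5), 1:5), "constant")
  expect_error(channel_accuracy(1:4, 1:5), "equal length")
})

test_that("Allan deviation shows the white-noise -1/2 slope, linear drift growth, and zero for constants", {
  set.seed(33)
  n <- 4096
  white <- channel_series(cbind(rnorm(n, 10, 0.5)), timestamps = 0:(n - 1))
  taus <- 2^(0:7)
  ad <- allan_deviation(white, taus)
  fit <- stats::lm(log10(ad$adev[, 1]) ~ log10(ad$tau))
  expect_lt(abs(unname(coef(fit)[2]) + 0.5), 0.1)
  # closed form for a pure ramp c*t: bin means step by c*tau -> adev = c*tau/sqrt(2)
  c0 <- 1e-3
  ramp <- channel_series(cbind(c0 * (0:(n - 1))), timestamps = 0:(n - 1))
  adr <- allan_deviation(ramp, taus)
  expect_equal(adr$adev[, 1], c0 * adr$tau / sqrt(2), tolerance = 1e-10)
  const <- channel_series(cbind(rep(2, n)), timestamps = 0:(n - 1))
  expect_equal(max(allan_deviation(const, taus)$adev), 0)
  expect_warning(allan_deviation(white, c(1, n)), "half the record")
})

test_that("drift measures the windowed mean shift in percent", {
  t <- 0:1799
  const <- channel_series(cbind(rep(5, 1800)), timestamps = t)
  expect_equal(drift(const, window = 60, span = 1740), 0)
  # 1 %/h ramp read over 30 min -> 0.5 %
  ramp <- channel_series(cbind(1 + 0.01 * t / 3600), timestamps = t)
  expect_equal(drift(ramp, window = 1, span = 1800 - 1), 0.5, tolerance = 1e-3)
  expect_error(drift(const, window = 60, span = 3600), "span")
})

test_that("ROI selection keeps pixels above a quarter of the maximum", {
  g <- matrix(0.2, 10, 10)
  g[5, 5] <- 1
  m <- roi_mask(g)
  expect_equal(sum(m), 1)
  expect_true(m[5, 5])
  gu <- matrix(1, 6, 6)
  expect_equal(sum(roi_mask(gu)), 36)        # uniform image -> whole grid
  expect_error(roi_mask(matrix(0, 4, 4)), "positive")
})

test_that("detectability follows the dB definition with an infinite sentinel for uniform ROIs", {
  g <- matrix(NA_real_, 8, 8)
  g[2:5, 2:5] <- 1
  expect_equal(detectability(g), Inf)
  set.seed(34)
  px <- rnorm(4000, 10, 1)            # mean = 10 sd -> 20 dB
  g2 <- matrix(px, 80, 50)
  expect_equal(detectability(g2, mask = matrix(TRUE, 80, 50)),
               20 * log10(mean(px) / sd(px)))
  expect_equal(detectability(g2, mask = matrix(TRUE, 80, 50)), 20,
               tolerance = 0.5)
  # distinguishability is the same statistic (empty-bath reference case)
  expect_equal(distinguishability(g2, matrix(TRUE, 80, 50)),
               detectability(g2, matrix(TRUE, 80, 50)))
})

test_that("figures of merit honour their defining identities", {
  m <- bath_mesh()
  p <- device_protocol()
  bg <- 1 / 0.194
  sig <- uniform_conductivity(m, bg)
  J <- compute_jacobian(m, sig, p)
  v0 <- solve_forward(m, sig, p)
  vt <- solve_forward(m, paint_targets(
    m, bg, data.frame(x = 30, y = 0, diameter = 50, ratio = 1e-6)), p)
  img <- reconstruct_difference(J, v0, vt, m)
  g <- rasterize(img)
  fom_self <- figures_of_merit(g, g)
  expect_equal(fom_self$position_error, 0)               # identical images
  expect_equal(fom_self$amplitude, mean(g[!is.na(g)]))
  expect_equal(fom_self$resolution, sqrt(sum(roi_mask(g)) / sum(!is.na(g))))
  # uniform positive image: ROI covers the disk, resolution 1, no ringing
  gu <- g
  gu[!is.na(gu)] <- 1
  fom_u <- figures_of_merit(gu, gu)
  expect_equal(fom_u$resolution, 1)
  expect_equal(fom_u$ringing, 0)
  # ROI-only amplitude switch
  expect_equal(figures_of_merit(g, g, amplitude_roi_only = TRUE)$amplitude,
               mean(g[roi_mask(g)]))
  expect_error(figures_of_merit(g, matrix(1, 2, 2)), "same grid")
})
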