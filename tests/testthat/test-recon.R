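test_that("zero difference reconstructs to exactly zero and lambda controls shrinkage", {
  m <- tiny_mesh()
  p <- tiny_protocol()
  sig <- uniform_conductivity(m, 1)
  J <- compute_jacobian(m, sig, p, current = 1)
  v <- solve_forward(m, sig, p, current = 1)
  img0 <- reconstruct_difference(J, v, v, m, sigma_ref = 1, current = 1)
  expect_equal(img0$element_values, rep(0, nrow(m$elements)))
  y <- v * (1 + 0.01 * sin(seq_along(v)))
  norms <- vapply(c(0.01, 1, 100, 1e4), function(l)
    sqrt(sum(reconstruct_difference(J, v, y, m, recon_config(lambda = l),
                                    sigma_ref = 1, current = 1)$element_values^2)),
    numeric(1))
  expect_true(all(diff(norms) < 0))     # ||x|| shrinks monotonically in lambda
})

test_that("reconstruction is linear in the difference vector", {
  m <- tiny_mesh()
  p <- tiny_protocol()
  sig <- uniform_conductivity(m, 1)
  J <- compute_jacobian(m, sig, p, current = 1)
  op <- reconstruction_operator(J, sigma_ref = 1, current = 1)
  v0 <- solve_forward(m, sig, p, current = 1)
  set.seed(2)
  y1 <- rnorm(length(v0), sd = 1e-3)
  y2 <- rnorm(length(v0), sd = 1e-3)
  r1 <- reconstruct_difference(op, v0, v0 + y1, m)$element_values
  r2 <- reconstruct_difference(op, v0, v0 + y2, m)$element_values
  r12 <- reconstruct_difference(op, v0, v0 + y1 + y2, m)$element_values
  expect_equal(r12, r1 + r2, tolerance = 1e-10)
})

test_that("the one-step solve agrees with an explicit dense-inverse oracle", {
  m <- tiny_mesh()
  p <- tiny_protocol()
  sig <- uniform_conductivity(m, 1)
  J <- compute_jacobian(m, sig, p, current = 1)
  cfg <- recon_config(lambda = 0.05, p = 0.5)
  v0 <- solve_forward(m, sig, p, current = 1)
  set.seed(4)
  vt <- v0 + rnorm(length(v0), sd = 1e-3)
  got <- reconstruct_difference(J, v0, vt, m, cfg, sigma_ref = 1,
                                current = 1)$element_values
  jtj <- crossprod(J)                      # sigma_ref = current = 1: Jn = J
  R <- diag(diag(jtj)^0.5)
  oracle <- -solve(jtj + 0.05 * R) %*% crossprod(J, vt - v0)
  expect_equal(got, as.numeric(oracle), tolerance = 1e-8)
})

test_that("an insulating inclusion appears positive, and the normalized mode matches plain up to weighting", {
  m <- bath_mesh()
  p <- device_protocol()
  bg <- 1 / 0.194
  sig <- uniform_conductivity(m, bg)
  J <- compute_jacobian(m, sig, p)
  v0 <- solve_forward(m, sig, p)
  st <- paint_targets(m, bg, data.frame(x = 40, y = 0, diameter = 50, ratio = 1e-6))
  vt <- solve_forward(m, st, p)
  img <- reconstruct_difference(J, v0, vt, m)
  # maximum element sits inside the target and is positive
  e_max <- which.max(img$element_values)
  expect_gt(img$element_values[e_max], 0)
  expect_lt(sqrt(sum((m$centroids[e_max, ] - c(40, 0))^2)), 25)
  imgn <- reconstruct_difference(J, v0, vt, m,
                                 recon_config(difference_mode = "normalized"))
  expect_gt(max(imgn$element_values), 0)
  expect_error(reconstruct_difference(J, v0 * 0, vt, m,
                                      recon_config(difference_mode = "normalized")),
               "positive")
})

test_that("mirror-symmetric targets reconstruct to mirror-symmetric images", {
  m <- bath_mesh()
  p <- device_protocol()
  bg <- 1 / 0.194
  sig <- uniform_conductivity(m, bg)
  J <- compute_jacobian(m, sig, p)
  op <- reconstruction_operator(J)
  v0 <- solve_forward(m, sig, p)
  img_pos <- reconstruct_difference(op, v0, solve_forward(
    m, paint_targets(m, bg, data.frame(x = 40, y = 0, diameter = 50,
                                       ratio = 1e-6)), p), m)
  img_neg <- reconstruct_difference(op, v0, solve_forward(
    m, paint_targets(m, bg, data.frame(x = -40, y = 0, diameter = 50,
                                       ratio = 1e-6)), p), m)
  g_pos <- rasterize(img_pos)
  g_neg <- rasterize(img_neg)
  flipped <- g_neg[nrow(g_neg):1, ]           # mirror across the y axis
  ok <- !is.na(g_pos) & !is.na(flipped)
  expect_gt(stats::cor(g_pos[ok], flipped[ok]), 0.999)
  # ROI-weighted centres of mass mirror each other (within discretization)
  com_p <- eittwin:::roi_centre_of_mass(g_pos, roi_mask(g_pos))
  com_n <- eittwin:::roi_centre_of_mass(g_neg, roi_mask(g_neg))
  expect_equal(com_p[["x"]], -com_n[["x"]], tolerance = 0.02)
  expect_lt(abs(com_p[["y"]]), 1)
  expect_lt(abs(com_n[["y"]]), 1)
})

test_that("rasterization paints the disk area and refines consistently", {
  m <- bath_mesh()
  vals <- rep(2.5, nrow(m$elements))
  g <- rasterize(vals, 64, mesh = m)
  inside <- !is.na(g)
  expect_true(all(g[inside] == 2.5))           # uniform field -> uniform pixels
  px_area <- attr(g, "pixel_size")^2
  expect_lt(abs(sum(inside) * px_area - pi * 120^2) / (pi * 120^2), 0.03)
  # out-of-disk pixels masked
  xs <- matrix(attr(g, "x"), 64, 64)
  ys <- matrix(attr(g, "y"), 64, 64, byrow = TRUE)
  expect_true(all(is.na(g[xs^2 + ys^2 > 120^2 * 1.01])))
  expect_error(rasterize(vals, 8, mesh = m), "grid_size")
})
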