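#' Reconstruction configuration
#'
#' @param lambda Regularization hyperparameter (> 0; 0.05 was chosen
#'   heuristically on the device to improve shape reconstruction and
#'   reduce ringing).
#' @param p Regularization exponent in `[0, 1]` applied to the diagonal of
#'   `t(J) %*% J` (0.5 by default, a compromise between pushing noise to
#'   the boundary and to the centre).
#' @param difference_mode `"plain"` (difference of magnitudes) or
#'   `"normalized"` (element-wise relative difference).
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(lambda = 0.05, p = 0.5,
                         difference_mode = c("plain", "normalized")) {
  stopifnot(lambda > 0, p >= 0, p <= 1)
  structure(list(lambda = lambda, p = p,
                 difference_mode = match.arg(difference_mode)),
            class = "recon_config")
}

#' Precompute the one-step linear reconstruction operator
#'
#' Forms the matrix `B = (t(Jn) Jn + lambda R)^-1 t(Jn)` with
#' `R = diag(diag(t(Jn) Jn)^p)`, where `Jn` is the Jacobian rescaled to
#' the dimensionless unit problem (`Jn = J * sigma_ref^2 / current`). The
#' regularization hyperparameters keep their conventional meaning on that
#' scale regardless of the physical drive current and background
#' conductivity; image amplitudes in difference imaging are relative, so
#' only this balance matters. The reconstruction of a difference vector
#' `y` is then `-B %*% y` (sign flipped so insulating targets are
#' positive).
#'
#' @param J Jacobian matrix from [compute_jacobian()] (rows =
#'   measurements, columns = elements).
#' @param config A [recon_config()].
#' @param sigma_ref Background conductivity the Jacobian was computed at
#'   (S/m).
#' @param current Drive current the Jacobian was computed at (A).
#' @return Matrix `B` (elements x measurements) of class
#'   `recon_operator` with the config attached.
#' @export
reconstruction_operator <- function(J, config = recon_config(),
                                    sigma_ref = 1 / 0.194, current = 98e-6) {
  stopifnot(inherits(config, "recon_config"), sigma_ref > 0, current > 0)
  jn <- J * sigma_ref^2 / current
  jtj <- crossprod(jn)
  r <- diag(jtj)^config$p
  lhs <- jtj + config$lambda * diag(r, nrow = ncol(jn))
  b <- solve(lhs, t(jn))
  attr(b, "config") <- config
  class(b) <- c("recon_operator", class(b))
  b
}

#' One-step regularized time-difference reconstruction
#'
#' Solves the Tikhonov-regularized normal equations
#' `(t(J) J + lambda R) x = t(J) y` with `R = diag(diag(t(J) J)^p)` and
#' `y` the (plain or normalized) difference between the target and
#' background measurement vectors, with the Jacobian rescaled to the
#' dimensionless unit problem (see [reconstruction_operator()]) so the
#' hyperparameters keep their conventional balance. The sign of the
#' solution is flipped so that a non-conductive (insulating) inclusion
#' appears positive, matching the target-bright display convention.
#'
#' @param J Jacobian matrix from [compute_jacobian()] (rows =
#'   measurements, columns = elements), or a precomputed
#'   [reconstruction_operator()].
#' @param v_background,v_target Measurement vectors (length = rows of
#'   `J`).
#' @param mesh The mesh the Jacobian was computed on (kept for
#'   rasterization and metrics).
#' @param config A [recon_config()].
#' @param sigma_ref,current Scaling of the Jacobian's physical units
#'   (ignored when `J` is already an operator).
#' @return Object of class `eit_image`: list with `element_values`
#'   (per-element conductivity-change estimate, target-positive), `mesh`,
#'   `config`.
#' @export
reconstruct_difference <- function(J, v_background, v_target, mesh,
                                   config = recon_config(),
                                   sigma_ref = 1 / 0.194, current = 98e-6) {
  stopifnot(inherits(config, "recon_config"))
  op <- if (inherits(J, "recon_operator")) J
        else reconstruction_operator(J, config, sigma_ref, current)
  if (inherits(J, "recon_operator") && !is.null(attr(op, "config")))
    config <- attr(op, "config")
  if (length(v_background) != ncol(op) || length(v_target) != ncol(op))
    stop("measurement vectors must match the Jacobian row count", call. = FALSE)
  if (!is.null(mesh) && nrow(op) != nrow(mesh$elements))
    stop("Jacobian column count must match the mesh element count", call. = FALSE)
  y <- switch(config$difference_mode,
              plain = v_target - v_background,
              normalized = {
                if (any(v_background <= 0))
                  stop("normalized mode requires strictly positive background", call. = FALSE)
                (v_target - v_background) / v_background
              })
  x <- op %*% y
  structure(list(element_values = -as.numeric(x), mesh = mesh,
                 config = config),
            class = "eit_image")
}

#' @export
print.eit_image <- function(x, ...) {
  cat(sprintf("EIT difference image: %d elements, range [%.3g, %.3g]\n",
              length(x$element_values), min(x$element_values),
              max(x$element_values)))
  invisible(x)
}

# pixel centre coordinates for a square grid covering the mesh bounding box
pixel_centres <- function(mesh, grid_size) {
  r <- mesh$radius
  px <- -r + (seq_len(grid_size) - 0.5) * 2 * r / grid_size
  list(x = px, y = px, size = 2 * r / grid_size)
}

# memoised pixel->element maps (keyed by mesh geometry and grid size)
.pixel_cache <- new.env(parent = emptyenv())

# map pixel centres to containing elements (NA outside the mesh)
locate_pixels <- function(mesh, grid_size) {
  key <- sprintf("r%g_e%d_ref%d_g%d", mesh$radius, mesh$n_electrodes,
                 mesh$refinement, grid_size)
  cached <- .pixel_cache[[key]]
  if (!is.null(cached)) return(cached)
  loc <- locate_pixels_impl(mesh, grid_size)
  .pixel_cache[[key]] <- loc
  loc
}

locate_pixels_impl <- function(mesh, grid_size) {
  pc <- pixel_centres(mesh, grid_size)
  xs <- rep(pc$x, times = grid_size)
  ys <- rep(pc$y, each = grid_size)
  assign_el <- rep(NA_integer_, grid_size^2)
  el <- mesh$elements
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  p2 <- mesh$nodes[el[, 2], , drop = FALSE]
  p3 <- mesh$nodes[el[, 3], , drop = FALSE]
  for (e in seq_len(nrow(el))) {
    xmin <- min(p1[e, 1], p2[e, 1], p3[e, 1]); xmax <- max(p1[e, 1], p2[e, 1], p3[e, 1])
    ymin <- min(p1[e, 2], p2[e, 2], p3[e, 2]); ymax <- max(p1[e, 2], p2[e, 2], p3[e, 2])
    cand <- which(xs >= xmin & xs <= xmax & ys >= ymin & ys <= ymax &
                    is.na(assign_el))
    if (!length(cand)) next
    d <- (p2[e, 1] - p1[e, 1]) * (p3[e, 2] - p1[e, 2]) -
      (p3[e, 1] - p1[e, 1]) * (p2[e, 2] - p1[e, 2])
    l1 <- ((p2[e, 1] - p1[e, 1]) * (ys[cand] - p1[e, 2]) -
             (p2[e, 2] - p1[e, 2]) * (xs[cand] - p1[e, 1])) / d
    l2 <- ((p1[e, 1] - p3[e, 1]) * (ys[cand] - p3[e, 2]) -
             (p1[e, 2] - p3[e, 2]) * (xs[cand] - p3[e, 1])) / d
    tol <- -1e-12
    inside <- l1 >= tol & l2 >= tol & (1 - l1 - l2) >= tol
    assign_el[cand[inside]] <- e
  }
  matrix(assign_el, nrow = grid_size, ncol = grid_size)
}

#' Rasterize an element image onto a square pixel grid
#'
#' Each pixel whose centre falls inside the meshed disk takes the value of
#' the element containing it; pixels outside are `NA` (masked). The
#' painted pixel area approximates the disk area (within about 3 % at
#' 64 x 64).
#'
#' @param image An `eit_image` (or a per-element numeric vector with
#'   `mesh` supplied).
#' @param grid_size Pixels per side (>= 16).
#' @param mesh Mesh override when `image` is a bare vector.
#' @return `grid_size` x `grid_size` numeric matrix with attributes `x`,
#'   `y` (pixel-centre coordinates in mm) and `pixel_size`; row index runs
#'   along x, column index along y.
#' @export
rasterize <- function(image, grid_size = 64L, mesh = NULL) {
  if (inherits(image, "eit_image")) {
    values <- image$element_values
    mesh <- image$mesh
  } else {
    values <- as.numeric(image)
  }
  stopifnot(!is.null(mesh), grid_size >= 16)
  if (length(values) != nrow(mesh$elements))
    stop("element values must match the mesh element count", call. = FALSE)
  loc <- locate_pixels(mesh, as.integer(grid_size))
  grid <- matrix(NA_real_, nrow = grid_size, ncol = grid_size)
  ok <- !is.na(loc)
  grid[ok] <- values[loc[ok]]
  pc <- pixel_centres(mesh, grid_size)
  attr(grid, "x") <- pc$x
  attr(grid, "y") <- pc$y
  attr(grid, "pixel_size") <- pc$size
  grid
}

#' Write a rasterized image as CSV
#'
#' @param grid A rasterized pixel grid (see [rasterize()]).
#' @param path Output path.
#' @export
write_image_csv <- function(grid, path) {
  utils::write.table(grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Plot an EIT image
#'
#' @param x An `eit_image`.
#' @param grid_size Raster resolution.
#' @param ... Passed to [graphics::image()].
#' @export
plot.eit_image <- function(x, grid_size = 64L, ...) {
  g <- rasterize(x, grid_size)
  graphics::image(attr(g, "x"), attr(g, "y"), g, asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}
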