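# Linear (P1) finite-element machinery for the 2-D conductivity equation
# div(sigma grad u) = 0 on the disk, with point-electrode current
# injection and insulating boundary elsewhere.

# Per-element P1 basis gradient coefficients: for element e with vertices
# (p1,p2,p3), grad(phi_i) = (b_i, c_i) constant on the element.
element_gradients <- function(mesh) {
  el <- mesh$elements
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  p2 <- mesh$nodes[el[, 2], , drop = FALSE]
  p3 <- mesh$nodes[el[, 3], , drop = FALSE]
  a2 <- 2 * mesh$areas
  b <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / a2
  cc <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / a2
  list(b = b, c = cc)
}

# Sparse global stiffness matrix for a per-element conductivity field.
fem_stiffness <- function(mesh, sigma) {
  g <- element_gradients(mesh)
  el <- mesh$elements
  n_el <- nrow(el)
  ii <- jj <- integer(9 * n_el)
  xx <- numeric(9 * n_el)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    idx <- k * n_el + seq_len(n_el)
    ii[idx] <- el[, i]
    jj[idx] <- el[, j]
    xx[idx] <- sigma * mesh$areas * (g$b[, i] * g$b[, j] + g$c[, i] * g$c[, j])
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
}

# Nodal potentials for unit current injected at each electrode (return
# through the grounded centre node). Column e: potential field for +1 A at
# electrode e. Pair injections/measurements are formed by differencing
# columns, so the ground return cancels.
electrode_potentials <- function(mesh, sigma) {
  K <- fem_stiffness(mesh, sigma)
  n <- nrow(mesh$nodes)
  free <- 2:n                        # ground the centre node
  Kf <- K[free, free]
  rhs <- matrix(0, n - 1L, mesh$n_electrodes)
  for (e in seq_len(mesh$n_electrodes))
    rhs[mesh$electrode_nodes[e] - 1L, e] <- 1
  uf <- as.matrix(Matrix::solve(Kf, rhs))
  u <- matrix(0, n, mesh$n_electrodes)
  u[free, ] <- uf
  u
}

#' Solve the forward problem for a measurement protocol
#'
#' Computes the boundary voltage for every drive/measure quadruple of a
#' protocol on a given conductivity field, using a linear FEM solution of
#' the 2-D conductivity equation with point-electrode current injection
#' (+I at drive+, -I at drive-) and an insulating boundary elsewhere.
#' By default the absolute voltage difference across the measurement pair
#' is returned, matching the device's demodulated magnitude output.
#'
#' @param mesh A [build_disk_mesh()] mesh.
#' @param sigma Per-element conductivity field (S/m, all positive).
#' @param protocol An `eit_protocol` for the mesh's electrode count.
#' @param current Drive current amplitude in amperes (the device's rated
#'   98 uA; the solution is linear in current).
#' @param signed Return signed voltage differences instead of magnitudes.
#' @return Numeric measurement vector, one value per protocol entry.
#' @export
solve_forward <- function(mesh, sigma, protocol, current = 98e-6,
                          signed = FALSE) {
  stopifnot(inherits(mesh, "disk_mesh"), inherits(protocol, "eit_protocol"))
  if (length(sigma) != nrow(mesh$elements))
    stop("sigma must have one value per mesh element", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("conductivities must be positive and finite", call. = FALSE)
  if (protocol_n_electrodes(protocol) > mesh$n_electrodes)
    stop("protocol references electrodes beyond the mesh", call. = FALSE)
  u <- electrode_potentials(mesh, sigma)
  en <- mesh$electrode_nodes
  drive <- current * (u[, protocol$v_plus, drop = FALSE] -
                        u[, protocol$v_minus, drop = FALSE])
  v <- drive[cbind(en[protocol$m_plus], seq_len(nrow(protocol)))] -
    drive[cbind(en[protocol$m_minus], seq_len(nrow(protocol)))]
  if (signed) v else abs(v)
}

#' Sensitivity (Jacobian) matrix at a background conductivity
#'
#' Adjoint-method sensitivities of the protocol measurements with respect
#' to each element's conductivity:
#' `J[m, e] = -integral_e grad(u_drive) . grad(u_measure) dA`, where
#' `u_drive` is the potential field of protocol row m's drive pair (at the
#' drive current) and `u_measure` the field of its measurement pair at
#' unit current. Rows are scaled by the sign of the corresponding signed
#' forward voltage so the Jacobian differentiates the device's magnitude
#' measurements (set `signed = TRUE` for the raw signed sensitivities).
#'
#' The homogeneity of the forward map (degree -1 in the conductivity)
#' gives the scaling identity `J %*% sigma = -v` at the linearization
#' point.
#'
#' @inheritParams solve_forward
#' @return Dense matrix, protocol rows x mesh elements.
#' @export
compute_jacobian <- function(mesh, sigma, protocol, current = 98e-6,
                             signed = FALSE) {
  stopifnot(inherits(mesh, "disk_mesh"), inherits(protocol, "eit_protocol"))
  if (length(sigma) != nrow(mesh$elements))
    stop("sigma must have one value per mesh element", call. = FALSE)
  if (any(sigma <= 0)) stop("conductivities must be positive", call. = FALSE)
  u <- electrode_potentials(mesh, sigma)
  g <- element_gradients(mesh)
  el <- mesh$elements
  # per-element gradient components of every electrode field
  gx <- g$b[, 1] * u[el[, 1], ] + g$b[, 2] * u[el[, 2], ] + g$b[, 3] * u[el[, 3], ]
  gy <- g$c[, 1] * u[el[, 1], ] + g$c[, 2] * u[el[, 2], ] + g$c[, 3] * u[el[, 3], ]
  dgx <- current * (gx[, protocol$v_plus, drop = FALSE] -
                      gx[, protocol$v_minus, drop = FALSE])
  dgy <- current * (gy[, protocol$v_plus, drop = FALSE] -
                      gy[, protocol$v_minus, drop = FALSE])
  mgx <- gx[, protocol$m_plus, drop = FALSE] - gx[, protocol$m_minus, drop = FALSE]
  mgy <- gy[, protocol$m_plus, drop = FALSE] - gy[, protocol$m_minus, drop = FALSE]
  J <- -t((dgx * mgx + dgy * mgy) * mesh$areas)
  if (!signed) {
    v_signed <- solve_forward(mesh, sigma, protocol, current, signed = TRUE)
    J <- J * sign(v_signed)
  }
  J
}

#' Analytic two-point-source solution on a homogeneous disk
#'
#' Closed-form boundary voltages for point current sources on the boundary
#' of a homogeneous disk (conductivity `sigma`, current `current` in at
#' drive+ and out at drive-): the potential is a sum of logarithmic
#' sources, u(p) = (I / (pi sigma)) * ln(|p - b| / |p - a|), giving the
#' measurement `u(m+) - u(m-)` per protocol entry. Serves as an
#' independent oracle for FEM convergence checks.
#'
#' @param radius Disk radius.
#' @param n_electrodes Electrode count (equally spaced, electrode 1 at
#'   angle 0).
#' @param protocol An `eit_protocol`.
#' @param sigma Homogeneous conductivity.
#' @param current Drive current.
#' @param signed Return signed values (default magnitudes).
#' @return Numeric measurement vector.
#' @export
analytic_disk_voltages <- function(radius, n_electrodes, protocol,
                                   sigma = 1, current = 1, signed = FALSE) {
  ang <- 2 * pi * (0:(n_electrodes - 1L)) / n_electrodes
  pts <- cbind(radius * cos(ang), radius * sin(ang))
  dist <- function(i, j) sqrt(rowSums((pts[i, , drop = FALSE] - pts[j, , drop = FALSE])^2))
  a <- protocol$v_plus; b <- protocol$v_minus
  cc <- protocol$m_plus; d <- protocol$m_minus
  v <- current / (pi * sigma) *
    (log(dist(cc, b) / dist(cc, a)) - log(dist(d, b) / dist(d, a)))
  if (signed) v else abs(v)
}
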