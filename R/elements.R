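#' Linear-elastic cartilage material
#'
#' Homogeneous, isotropic, linearly elastic model. Septal cartilage defaults:
#' E = 5 MPa (mid-range of reported tensile moduli), nu = 0.32,
#' rho = 2000 kg/m^3 (cartilage is ~75% water plus dense collagen /
#' proteoglycan).
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio, dimensionless, in [0, 0.5).
#' @param rho Density, kg/m^3.
#' @return A \code{septum_material} list.
#' @export
#' @examples
#' cartilage_material()
cartilage_material <- function(E = 5e6, nu = 0.32, rho = 2000) {
  if (E <= 0) stop("E must be positive")
  if (nu < 0 || nu >= 0.5) stop("nu must lie in [0, 0.5)")
  if (rho <= 0) stop("rho must be positive")
  structure(list(E = E, nu = nu, rho = rho), class = "septum_material")
}

# plane-stress constitutive matrix
plane_stress_D <- function(mat) {
  mat$E / (1 - mat$nu^2) *
    matrix(c(1, mat$nu, 0, mat$nu, 1, 0, 0, 0, (1 - mat$nu) / 2), 3, 3)
}

#' Flexural rigidity D = E t^3 / (12 (1 - nu^2)) of a thin plate
#' @param mat A \code{septum_material}.
#' @param thickness Plate thickness, m.
#' @return Rigidity in N m.
#' @export
flexural_rigidity <- function(mat, thickness) {
  mat$E * thickness^3 / (12 * (1 - mat$nu^2))
}

#' Tip-spring stiffness from the lower-lateral-cartilage cantilever
#'
#' The paired tip cartilages behave as an end-loaded cantilever of
#' rectangular cross-section; the equivalent spring constant is
#' k = 3 E I / L^3 with I = w h^3 / 12, i.e. k = E w h^3 / (4 L^3).
#'
#' @param E Young's modulus of the cantilever, Pa.
#' @param width,height Cross-section width and height, m.
#' @param length Cantilever length, m.
#' @return Stiffness in N/m.
#' @export
#' @examples
#' tip_spring_from_cantilever(5e6, 4e-3, 10e-3, 20e-3)  # 625 N/m
tip_spring_from_cantilever <- function(E, width, height, length) {
  if (any(c(E, width, height, length) <= 0))
    stop("all cantilever parameters must be positive")
  E * width * height^3 / (4 * length^3)
}

#' Grounded tip spring
#'
#' Spring support of the nasal tip (ASA node) acting along the three
#' orthogonal axes, grounded at the attachment. Default 20 kN/m per axis.
#'
#' @param k Stiffness per axis, N/m (>= 0; 0 disables the spring).
#' @return A \code{tip_spring} list.
#' @export
tip_spring <- function(k = 20e3) {
  if (k < 0) stop("spring stiffness must be non-negative")
  structure(list(k = k), class = "tip_spring")
}

tri_coords_check <- function(xy) {
  A <- tri_area(xy)
  if (A <= 0) stop("degenerate or negatively oriented triangle (area ", A, ")")
  A
}

#' Constant-strain-triangle membrane stiffness (6 x 6)
#'
#' Plane-stress CST element; DOFs (u1, v1, u2, v2, u3, v3).
#'
#' @param xy 3 x 2 vertex coordinates, m, counter-clockwise.
#' @param mat A \code{septum_material}.
#' @param thickness Element thickness, m.
#' @return Symmetric 6 x 6 stiffness matrix, N/m.
#' @export
element_membrane_stiffness <- function(xy, mat, thickness) {
  A <- tri_coords_check(xy)
  B <- cst_B(xy, A)
  thickness * A * t(B) %*% plane_stress_D(mat) %*% B
}

# CST strain-displacement matrix (3 x 6)
cst_B <- function(xy, A = tri_area(xy)) {
  x <- xy[, 1]; y <- xy[, 2]
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  c_ <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- b
  B[2, c(2, 4, 6)] <- c_
  B[3, c(1, 3, 5)] <- c_
  B[3, c(2, 4, 6)] <- b
  B / (2 * A)
}

# consistent mass pattern of the linear triangle, one field
.tri_mass_pattern <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3) / 12

# membrane consistent mass (6 x 6), linear interpolation of u and v
element_membrane_mass <- function(xy, mat, thickness) {
  A <- tri_coords_check(xy)
  m <- mat$rho * thickness * A * .tri_mass_pattern
  M <- matrix(0, 6, 6)
  M[c(1, 3, 5), c(1, 3, 5)] <- m
  M[c(2, 4, 6), c(2, 4, 6)] <- m
  M
}

# DKT side constants for sides 4 (nodes 2-3), 5 (3-1), 6 (1-2)
dkt_side_constants <- function(xy) {
  i <- c(2L, 3L, 1L); j <- c(3L, 1L, 2L)
  xij <- xy[i, 1] - xy[j, 1]
  yij <- xy[i, 2] - xy[j, 2]
  l2 <- xij^2 + yij^2
  list(P = -6 * xij / l2, t = -6 * yij / l2,
       q = 3 * xij * yij / l2, r = 3 * yij^2 / l2)
}

# derivatives of the DKT rotation interpolants Hx, Hy with respect to the
# area coordinates (xi, eta); returns a 4 x 9 matrix (rows: Hx,xi Hy,xi
# Hx,eta Hy,eta) following the classic explicit formulation
dkt_H_derivs <- function(sc, xi, eta) {
  P4 <- sc$P[1]; P5 <- sc$P[2]; P6 <- sc$P[3]
  t4 <- sc$t[1]; t5 <- sc$t[2]; t6 <- sc$t[3]
  q4 <- sc$q[1]; q5 <- sc$q[2]; q6 <- sc$q[3]
  r4 <- sc$r[1]; r5 <- sc$r[2]; r6 <- sc$r[3]

  Hx_xi <- c(
    P6 * (1 - 2 * xi) + (P5 - P6) * eta,
    q6 * (1 - 2 * xi) - (q5 + q6) * eta,
    -4 + 6 * (xi + eta) + r6 * (1 - 2 * xi) - eta * (r5 + r6),
    -P6 * (1 - 2 * xi) + eta * (P4 + P6),
    q6 * (1 - 2 * xi) - eta * (q6 - q4),
    -2 + 6 * xi + r6 * (1 - 2 * xi) + eta * (r4 - r6),
    -eta * (P5 + P4),
    eta * (q4 - q5),
    -eta * (r5 - r4))

  Hy_xi <- c(
    t6 * (1 - 2 * xi) + eta * (t5 - t6),
    1 + r6 * (1 - 2 * xi) - eta * (r5 + r6),
    -q6 * (1 - 2 * xi) + eta * (q5 + q6),
    -t6 * (1 - 2 * xi) + eta * (t4 + t6),
    -1 + r6 * (1 - 2 * xi) + eta * (r4 - r6),
    -q6 * (1 - 2 * xi) - eta * (q4 - q6),
    -eta * (t4 + t5),
    eta * (r4 - r5),
    -eta * (q4 - q5))

  Hx_eta <- c(
    -P5 * (1 - 2 * eta) - xi * (P6 - P5),
    q5 * (1 - 2 * eta) - xi * (q5 + q6),
    -4 + 6 * (xi + eta) + r5 * (1 - 2 * eta) - xi * (r5 + r6),
    xi * (P4 + P6),
    xi * (q4 - q6),
    -xi * (r6 - r4),
    P5 * (1 - 2 * eta) - xi * (P4 + P5),
    q5 * (1 - 2 * eta) + xi * (q4 - q5),
    -2 + 6 * eta + r5 * (1 - 2 * eta) + xi * (r4 - r5))

  Hy_eta <- c(
    -t5 * (1 - 2 * eta) - xi * (t6 - t5),
    1 + r5 * (1 - 2 * eta) - xi * (r5 + r6),
    -q5 * (1 - 2 * eta) + xi * (q5 + q6),
    xi * (t4 + t6),
    xi * (r4 - r6),
    -xi * (q4 - q6),
    t5 * (1 - 2 * eta) - xi * (t4 + t5),
    -1 + r5 * (1 - 2 * eta) + xi * (r4 - r5),
    -q5 * (1 - 2 * eta) - xi * (q4 - q5))

  rbind(Hx_xi, Hy_xi, Hx_eta, Hy_eta)
}

# DKT curvature-displacement matrix B (3 x 9) at area coordinates (xi, eta);
# DOFs per node are (w, thx, thy) with thx = dw/dy and thy = -dw/dx
dkt_B <- function(xy, xi, eta, sc = dkt_side_constants(xy),
                  A = tri_area(xy)) {
  x31 <- xy[3, 1] - xy[1, 1]; y31 <- xy[3, 2] - xy[1, 2]
  x12 <- xy[1, 1] - xy[2, 1]; y12 <- xy[1, 2] - xy[2, 2]
  H <- dkt_H_derivs(sc, xi, eta)
  rbind(
    y31 * H[1, ] + y12 * H[3, ],
    -x31 * H[2, ] - x12 * H[4, ],
    -x31 * H[1, ] - x12 * H[3, ] + y31 * H[2, ] + y12 * H[4, ]
  ) / (2 * A)
}

#' Discrete-Kirchhoff-triangle bending stiffness (9 x 9)
#'
#' Thin-plate (Kirchhoff) bending element after Batoz's explicit DKT
#' formulation; exact 3-point mid-side integration. DOFs per node are
#' (w, thx, thy) with thx = dw/dy (rotation about x) and thy = -dw/dx
#' (rotation about y).
#'
#' @inheritParams element_membrane_stiffness
#' @return Symmetric 9 x 9 stiffness matrix.
#' @export
element_bending_stiffness <- function(xy, mat, thickness) {
  A <- tri_coords_check(xy)
  Db <- flexural_rigidity(mat, thickness) *
    matrix(c(1, mat$nu, 0, mat$nu, 1, 0, 0, 0, (1 - mat$nu) / 2), 3, 3)
  sc <- dkt_side_constants(xy)
  K <- matrix(0, 9, 9)
  gp <- rbind(c(0.5, 0), c(0.5, 0.5), c(0, 0.5))
  for (g in 1:3) {
    B <- dkt_B(xy, gp[g, 1], gp[g, 2], sc, A)
    K <- K + (2 * A / 6) * t(B) %*% Db %*% B
  }
  (K + t(K)) / 2
}

# bending consistent mass (9 x 9): translational inertia rho t on w (linear
# interpolation) and rotary inertia rho t^3/12 on each rotation
element_bending_mass <- function(xy, mat, thickness) {
  A <- tri_coords_check(xy)
  mw <- mat$rho * thickness * A * .tri_mass_pattern
  mr <- mat$rho * thickness^3 / 12 * A * .tri_mass_pattern
  M <- matrix(0, 9, 9)
  M[c(1, 4, 7), c(1, 4, 7)] <- mw
  M[c(2, 5, 8), c(2, 5, 8)] <- mr
  M[c(3, 6, 9), c(3, 6, 9)] <- mr
  M
}

#' Element geometric (initial-stress) stiffness on transverse DOFs (3 x 3)
#'
#' Integral of t (grad w)^T sigma (grad w) over the element with linear
#' interpolation of w; sigma is the constant membrane stress of the element.
#'
#' @param xy 3 x 2 vertex coordinates, m, counter-clockwise.
#' @param thickness Element thickness, m.
#' @param sigma Length-3 membrane stress (sigma_xx, sigma_yy, tau_xy), Pa.
#' @return Symmetric 3 x 3 matrix acting on the element's w DOFs.
#' @export
element_geometric_stiffness <- function(xy, thickness, sigma) {
  A <- tri_coords_check(xy)
  x <- xy[, 1]; y <- xy[, 2]
  G <- rbind(c(y[2] - y[3], y[3] - y[1], y[1] - y[2]),
             c(x[3] - x[2], x[1] - x[3], x[2] - x[1])) / (2 * A)
  S <- matrix(c(sigma[1], sigma[3], sigma[3], sigma[2]), 2, 2)
  thickness * A * t(G) %*% S %*% G
}
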