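#' In-plane load case for the static preload step
#'
#' Two frontal-trauma loadings are modelled, both strictly in-plane (only
#' in-plane loading affects the eigenmodes of a flat plate):
#' \describe{
#'   \item{\code{anteroposterior_couple}}{a force couple at the two nodes
#'     flanking the tip: equal and opposite point forces with components of
#'     \code{force_magnitude} in each axis, (-F, -F) at the dorsal-side
#'     neighbour and (+F, +F) at the caudal-side neighbour. The couple has
#'     zero net force and non-zero moment; a variant with a net posterior
#'     push can be requested through the \code{f_dorsal}/\code{f_caudal}
#'     arguments of [build_load_vector()] (a net push at the free thin
#'     plate corner buckles the linearized prestressed operator).}
#'   \item{\code{dorsal_caudal_pressure}}{uniform inward traction of
#'     \code{pressure_magnitude} x thickness (N/m) integrated consistently
#'     along the dorsal and caudal free edges.}
#' }
#'
#' @param kind \code{"anteroposterior_couple"} or
#'   \code{"dorsal_caudal_pressure"}.
#' @param force_magnitude Per-axis point-force magnitude, N (default 1).
#' @param pressure_magnitude Edge pressure, Pa (default 2000).
#' @return A \code{load_case} list.
#' @export
load_case <- function(kind = c("anteroposterior_couple", "dorsal_caudal_pressure"),
                      force_magnitude = 1, pressure_magnitude = 2000) {
  kind <- match.arg(kind)
  if (force_magnitude < 0 || pressure_magnitude < 0)
    stop("load magnitudes must be non-negative")
  structure(list(kind = kind, force_magnitude = force_magnitude,
                 pressure_magnitude = pressure_magnitude),
            class = "load_case")
}

# the two boundary nodes adjacent to the tip, named by the free edge they
# sit on
tip_neighbours <- function(mesh) {
  tip <- mesh$node_sets$tip
  be <- mesh$boundary_edges
  inc <- be[be$n1 == tip | be$n2 == tip, ]
  if (nrow(inc) < 2) stop("mesh lacks the two boundary edges at the tip")
  other <- ifelse(inc$n1 == tip, inc$n2, inc$n1)
  stats::setNames(other, inc$label)
}

#' Build the membrane force vector of a load case
#'
#' @param mesh A \code{septum_mesh}.
#' @param case A [load_case()].
#' @param f_dorsal,f_caudal Length-2 force vectors (N) applied at the
#'   dorsal- and caudal-side tip neighbours in the couple case; defaults
#'   give the pure couple (-F, -F) / (+F, +F). Override to explore other
#'   couple geometries.
#' @return Numeric vector of length 2 x n_nodes (u, v interleaved), N.
#' @export
build_load_vector <- function(mesh, case,
                              f_dorsal = c(-1, -1) * case$force_magnitude,
                              f_caudal = c(1, 1) * case$force_magnitude) {
  stopifnot(inherits(case, "load_case"))
  f <- numeric(2L * nrow(mesh$nodes))
  if (case$kind == "anteroposterior_couple") {
    nb <- tip_neighbours(mesh)
    if (!all(c("dorsal_free", "caudal_free") %in% names(nb)))
      stop("tip is not flanked by dorsal_free and caudal_free edges")
    nd <- nb[["dorsal_free"]]; nc <- nb[["caudal_free"]]
    f[c(2L * nd - 1L, 2L * nd)] <- f_dorsal
    f[c(2L * nc - 1L, 2L * nc)] <- f_caudal
  } else {
    be <- mesh$boundary_edges
    sel <- be$label %in% c("dorsal_free", "caudal_free")
    if (!any(sel)) stop("mesh has no dorsal_free/caudal_free boundary edges")
    p <- case$pressure_magnitude
    tris <- mesh$triangles
    for (r in which(sel)) {
      n1 <- be$n1[r]; n2 <- be$n2[r]
      d <- mesh$nodes[n2, ] - mesh$nodes[n1, ]
      L <- sqrt(sum(d^2))
      inward <- c(-d[2], d[1]) / L       # ccw boundary: left side is interior
      e <- which(rowSums(matrix(tris %in% c(n1, n2), nrow(tris), 3)) == 2)[1]
      tt <- mesh$thickness[e]
      fe <- p * tt * L / 2 * inward
      f[c(2L * n1 - 1L, 2L * n1)] <- f[c(2L * n1 - 1L, 2L * n1)] + fe
      f[c(2L * n2 - 1L, 2L * n2)] <- f[c(2L * n2 - 1L, 2L * n2)] + fe
    }
  }
  f
}

#' Solve the static in-plane (membrane) preload step
#'
#' Direct sparse solve of Km u = f on the free membrane DOFs, followed by
#' constant-per-element stress recovery sigma = D B u_e and the plane-stress
#' von Mises stress sqrt(sxx^2 - sxx syy + syy^2 + 3 txy^2).
#'
#' @param sys A \code{septum_system}.
#' @param f Full-length membrane force vector (2 x n_nodes), N.
#' @return A \code{membrane_state}: \code{u} (full displacement vector, m),
#'   \code{stress} (n_elem x 3: sxx, syy, txy, Pa), \code{von_mises}
#'   (n_elem, Pa), \code{residual} (relative).
#' @export
solve_membrane_static <- function(sys, f) {
  stopifnot(inherits(sys, "septum_system"))
  if (length(f) != nrow(sys$Km)) stop("force vector does not conform to the membrane DOFs")
  Kf <- sys$Km[sys$free_m, sys$free_m, drop = FALSE]
  ff <- f[sys$free_m]
  uf <- as.numeric(Matrix::solve(Kf, ff))
  u <- numeric(length(f))
  u[sys$free_m] <- uf
  res_num <- sqrt(sum((as.numeric(Kf %*% uf) - ff)^2))
  res <- if (sum(ff^2) > 0) res_num / sqrt(sum(ff^2)) else 0

  mesh <- sys$mesh; D <- plane_stress_D(sys$material)
  ne <- nrow(mesh$triangles)
  stress <- matrix(0, ne, 3, dimnames = list(NULL, c("sxx", "syy", "txy")))
  for (e in seq_len(ne)) {
    tr <- mesh$triangles[e, ]
    ue <- u[membrane_dofs(tr)]
    stress[e, ] <- as.numeric(D %*% cst_B(mesh$nodes[tr, , drop = FALSE]) %*% ue)
  }
  vm <- sqrt(pmax(0, stress[, 1]^2 - stress[, 1] * stress[, 2] +
                    stress[, 2]^2 + 3 * stress[, 3]^2))
  structure(list(u = u, stress = stress, von_mises = vm, residual = res),
            class = "membrane_state")
}

#' Assemble the geometric (initial-stress) stiffness of a membrane state
#'
#' Sparse operator on the bending DOF layout (3 DOF/node) with non-zeros
#' only on transverse-displacement (w) DOFs:
#' Kg = sum_e t_e A_e G_e^T sigma_e G_e. Linear in the stress state.
#'
#' @param mesh A \code{septum_mesh}.
#' @param state A \code{membrane_state} (or a n_elem x 3 stress matrix).
#' @return Sparse symmetric 3n x 3n matrix.
#' @export
assemble_geometric_stiffness <- function(mesh, state) {
  stress <- if (inherits(state, "membrane_state")) state$stress else state
  if (!is.matrix(stress) || nrow(stress) != nrow(mesh$triangles) || ncol(stress) != 3)
    stop("stress state must provide one (sxx, syy, txy) row per element")
  ne <- nrow(mesh$triangles)
  nd <- 3L * nrow(mesh$nodes)
  ii <- integer(ne * 9L); jj <- integer(ne * 9L); xx <- numeric(ne * 9L)
  pos <- 0L
  for (e in seq_len(ne)) {
    tr <- mesh$triangles[e, ]
    Kge <- element_geometric_stiffness(mesh$nodes[tr, , drop = FALSE],
                                       mesh$thickness[e], stress[e, ])
    dofs <- w_dofs(tr)
    idx <- pos + 1:9
    ii[idx] <- rep(dofs, times = 3L)
    jj[idx] <- rep(dofs, each = 3L)
    xx[idx] <- as.vector(Kge)
    pos <- pos + 9L
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nd, nd))
  Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
}
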