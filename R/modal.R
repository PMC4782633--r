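# dense generalized symmetric eigensolve K phi = lambda M phi on free DOFs;
# M is reduced by Cholesky congruence so eigenvectors come out
# mass-normalized (phi' M phi = 1). Deterministic (LAPACK, no randomness).
solve_gevp_dense <- function(K, M, n_modes) {
  K <- as.matrix(K); M <- as.matrix(M)
  n <- nrow(K)
  if (n_modes < 1) stop("n_modes must be at least 1")
  if (n_modes > n) stop("requested ", n_modes, " modes from a system with only ", n, " DOFs")
  R <- tryCatch(chol(M), error = function(e)
    stop("mass operator is not positive definite: ", conditionMessage(e)))
  # A = R^-T K R^-1 (congruent, same eigenvalues)
  X <- backsolve(R, K, transpose = TRUE)
  A <- backsolve(R, t(X), transpose = TRUE)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)        # eigenvalues in decreasing order
  sel <- n - seq_len(n_modes) + 1L       # the n_modes smallest
  lambda <- e$values[sel]
  if (any(lambda <= 0)) {
    if (min(lambda) < -1e-6 * max(abs(e$values)))
      stop("buckled under preload: the prestressed stiffness has a negative eigenvalue")
    stop("non-positive eigenvalue encountered; system has an unconstrained rigid-body mode")
  }
  phi <- backsolve(R, e$vectors[, sel, drop = FALSE])
  list(lambda = lambda, phi = phi)
}

new_mode_set <- function(frequency, family, shapes, n_nodes) {
  structure(list(frequency = frequency, family = family,
                 shapes = shapes, n_nodes = n_nodes),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("Mode set:", length(x$frequency), "modes\n")
  print(data.frame(mode = seq_along(x$frequency),
                   frequency_hz = round(x$frequency, 2),
                   family = x$family))
  invisible(x)
}

#' Bending (transverse) natural modes of the prestressed plate
#'
#' Solves (Kb + Kg) phi = omega^2 Mb phi on the free bending DOFs and
#' returns the lowest \code{n_modes} mass-normalized modes. Shape vectors
#' are re-embedded into the full 3-DOF/node layout with zeros on fixed DOFs.
#'
#' @param sys A \code{septum_system}.
#' @param Kg Geometric stiffness from [assemble_geometric_stiffness()], or
#'   \code{NULL} for the unstressed plate.
#' @param n_modes Number of modes (default 10).
#' @return A \code{mode_set} with family \code{"bending"}.
#' @export
solve_bending_modes <- function(sys, Kg = NULL, n_modes = 10) {
  stopifnot(inherits(sys, "septum_system"))
  K <- sys$Kb
  if (!is.null(Kg)) {
    if (!all(dim(Kg) == dim(K))) stop("geometric stiffness does not conform to the bending DOFs")
    K <- K + Kg
  }
  sol <- solve_gevp_dense(K[sys$free_b, sys$free_b, drop = FALSE],
                          sys$Mb[sys$free_b, sys$free_b, drop = FALSE], n_modes)
  nfull <- nrow(sys$Kb)
  shapes <- lapply(seq_len(n_modes), function(k) {
    v <- numeric(nfull); v[sys$free_b] <- sol$phi[, k]; v
  })
  new_mode_set(sqrt(sol$lambda) / (2 * pi), rep("bending", n_modes),
               shapes, nrow(sys$mesh$nodes))
}

#' Membrane (in-plane) natural modes
#'
#' Solves Km phi = omega^2 Mm phi on the free membrane DOFs. These modes
#' carry no transverse displacement and appear as "in-plane" (dash) entries
#' in the deviation-type table.
#'
#' @inheritParams solve_bending_modes
#' @return A \code{mode_set} with family \code{"membrane"}.
#' @export
solve_membrane_modes <- function(sys, n_modes = 10) {
  stopifnot(inherits(sys, "septum_system"))
  sol <- solve_gevp_dense(sys$Km[sys$free_m, sys$free_m, drop = FALSE],
                          sys$Mm[sys$free_m, sys$free_m, drop = FALSE], n_modes)
  nfull <- nrow(sys$Km)
  shapes <- lapply(seq_len(n_modes), function(k) {
    v <- numeric(nfull); v[sys$free_m] <- sol$phi[, k]; v
  })
  new_mode_set(sqrt(sol$lambda) / (2 * pi), rep("membrane", n_modes),
               shapes, nrow(sys$mesh$nodes))
}

#' Merge the bending and membrane families into one frequency-ordered set
#'
#' Stable merge of the two families keeping the \code{n} globally lowest
#' frequencies; exact frequency ties are broken bending-first, then by
#' within-family order.
#'
#' @param bending,membrane \code{mode_set}s (either may have zero modes).
#' @param n Number of modes to keep (default 10).
#' @return A \code{mode_set} with mixed families.
#' @export
merge_and_sort <- function(bending, membrane, n = 10) {
  freq <- c(bending$frequency, membrane$frequency)
  fam <- c(bending$family, membrane$family)
  shp <- c(bending$shapes, membrane$shapes)
  if (length(freq) < n)
    stop("fewer than ", n, " modes available (", length(freq), ")")
  fam_rank <- ifelse(fam == "bending", 0L, 1L)
  within <- c(seq_along(bending$frequency), seq_along(membrane$frequency))
  ord <- order(freq, fam_rank, within)[seq_len(n)]
  new_mode_set(freq[ord], fam[ord], shp[ord],
               bending$n_nodes %||% membrane$n_nodes)
}

# relative eigen-residual ||K phi - lambda M phi|| / ||K phi|| for checking
mode_residual <- function(K, M, phi, freq) {
  lambda <- (2 * pi * freq)^2
  r <- as.numeric(K %*% phi - lambda * (M %*% phi))
  sqrt(sum(r^2)) / sqrt(sum(as.numeric(K %*% phi)^2))
}

#' Residual check of a computed mode set against its operators
#'
#' @param modes A \code{mode_set} (single family).
#' @param K,M The full operators the modes were computed from.
#' @param free Free-DOF index map used in the solve.
#' @return Numeric vector of relative residuals, one per mode.
#' @export
mode_residuals <- function(modes, K, M, free) {
  vapply(seq_along(modes$frequency), function(k) {
    mode_residual(K[free, free, drop = FALSE], M[free, free, drop = FALSE],
                  modes$shapes[[k]][free], modes$frequency[k])
  }, numeric(1))
}
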