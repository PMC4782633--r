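# global DOF maps: membrane node i -> (2i-1, 2i) = (u, v);
# bending node i -> (3i-2, 3i-1, 3i) = (w, thx, thy)
membrane_dofs <- function(nodes) as.vector(rbind(2L * nodes - 1L, 2L * nodes))
bending_dofs <- function(nodes) as.vector(rbind(3L * nodes - 2L, 3L * nodes - 1L, 3L * nodes))
w_dofs <- function(nodes) 3L * nodes - 2L

# assemble a global sparse operator from per-element dense matrices
assemble_operator <- function(mesh, elem_fun, dof_per_node) {
  ne <- nrow(mesh$triangles)
  nd <- dof_per_node * nrow(mesh$nodes)
  blk <- (3L * dof_per_node)^2
  ii <- integer(ne * blk); jj <- integer(ne * blk); xx <- numeric(ne * blk)
  pos <- 0L
  for (e in seq_len(ne)) {
    tr <- mesh$triangles[e, ]
    Ke <- elem_fun(mesh$nodes[tr, , drop = FALSE], mesh$thickness[e])
    dofs <- if (dof_per_node == 2L) membrane_dofs(tr) else bending_dofs(tr)
    idx <- pos + seq_len(blk)
    ii[idx] <- rep(dofs, times = length(dofs))
    jj[idx] <- rep(dofs, each = length(dofs))
    xx[idx] <- as.vector(Ke)
    pos <- pos + blk
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nd, nd))
  Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
}

#' Assemble the global membrane and bending operators of the septum plate
#'
#' Builds the decoupled membrane (CST, 2 DOF/node) and bending (DKT,
#' 3 DOF/node) stiffness and consistent mass operators, adds the grounded
#' tip spring (u, v and w diagonals of the tip node), and eliminates the
#' DOFs of the rigidly fixed bony interfaces. For a flat midplane the two
#' families are exactly decoupled; they interact only through the geometric
#' stiffness of a membrane preload (see
#' [assemble_geometric_stiffness()]).
#'
#' @param mesh A \code{septum_mesh}.
#' @param material A \code{septum_material}.
#' @param spring A \code{tip_spring} or \code{NULL} for a free tip.
#' @param fixed_labels Node-set labels whose nodes are rigidly fixed
#'   (default: all four bony interfaces).
#' @param ss_labels Node-set labels constrained as simply supported
#'   (transverse displacement w fixed, rotations free); used by the
#'   analytic plate fixtures.
#' @return A \code{septum_system}: sparse symmetric \code{Km}, \code{Mm}
#'   (2n x 2n), \code{Kb}, \code{Mb} (3n x 3n) on the full DOF sets, plus
#'   \code{free_m}, \code{free_b} index maps of unconstrained DOFs.
#' @export
assemble_system <- function(mesh, material, spring = NULL,
                            fixed_labels = c("nasal_bone", "ethmoid",
                                             "vomer", "hard_palate"),
                            ss_labels = character()) {
  stopifnot(inherits(mesh, "septum_mesh"), inherits(material, "septum_material"))
  known <- names(mesh$node_sets)
  bad <- setdiff(c(fixed_labels, ss_labels), known)
  if (length(bad)) stop("unknown node-set label(s): ", paste(bad, collapse = ", "))

  Km <- assemble_operator(mesh, function(xy, t) element_membrane_stiffness(xy, material, t), 2L)
  Mm <- assemble_operator(mesh, function(xy, t) element_membrane_mass(xy, material, t), 2L)
  Kb <- assemble_operator(mesh, function(xy, t) element_bending_stiffness(xy, material, t), 3L)
  Mb <- assemble_operator(mesh, function(xy, t) element_bending_mass(xy, material, t), 3L)

  if (!is.null(spring)) {
    stopifnot(inherits(spring, "tip_spring"))
    tip <- mesh$node_sets$tip
    if (is.null(tip) || !length(tip)) stop("mesh has no tip node set for the spring")
    md <- membrane_dofs(tip)
    Km[cbind(md, md)] <- Km[cbind(md, md)] + spring$k
    wd <- w_dofs(tip)
    Kb[cbind(wd, wd)] <- Kb[cbind(wd, wd)] + spring$k
  }

  fixed_nodes <- sort(unique(unlist(mesh$node_sets[fixed_labels], use.names = FALSE)))
  ss_nodes <- sort(unique(unlist(mesh$node_sets[ss_labels], use.names = FALSE)))
  nm <- 2L * nrow(mesh$nodes); nb <- 3L * nrow(mesh$nodes)
  drop_m <- membrane_dofs(fixed_nodes)
  drop_b <- c(bending_dofs(fixed_nodes), w_dofs(setdiff(ss_nodes, fixed_nodes)))
  free_m <- setdiff(seq_len(nm), drop_m)
  free_b <- setdiff(seq_len(nb), sort(drop_b))
  if (!length(free_m) || !length(free_b))
    stop("no free DOFs remain after applying the boundary conditions")

  structure(list(
    Km = Km, Mm = Mm, Kb = Kb, Mb = Mb,
    free_m = free_m, free_b = free_b,
    mesh = mesh, material = material, spring = spring,
    fixed_labels = fixed_labels, ss_labels = ss_labels
  ), class = "septum_system")
}

#' @export
print.septum_system <- function(x, ...) {
  cat("Assembled septum plate system:", nrow(x$mesh$nodes), "nodes;",
      length(x$free_m), "free membrane DOFs,",
      length(x$free_b), "free bending DOFs;",
      if (is.null(x$spring)) "free tip" else
        sprintf("tip spring %.3g N/m", x$spring$k), "\n")
  invisible(x)
}

# constrained (free-DOF) views of the four operators
constrained_operators <- function(sys) {
  list(
    Km = sys$Km[sys$free_m, sys$free_m, drop = FALSE],
    Mm = sys$Mm[sys$free_m, sys$free_m, drop = FALSE],
    Kb = sys$Kb[sys$free_b, sys$free_b, drop = FALSE],
    Mb = sys$Mb[sys$free_b, sys$free_b, drop = FALSE]
  )
}
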