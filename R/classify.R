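.bony_labels <- c("nasal_bone", "ethmoid", "vomer", "hard_palate")

#' Transverse (out-of-plane) fraction of a mode's modal mass
#'
#' Ratio of the modal mass carried by transverse displacement w to the
#' total modal mass. For the flat decoupled plate this is ~1 for bending
#' modes (up to the small rotary-inertia share) and exactly 0 for membrane
#' modes; intermediate values only arise for synthetic mixed vectors.
#'
#' @param shape_bending Full bending-layout vector (3 DOF/node) or NULL.
#' @param shape_membrane Full membrane-layout vector (2 DOF/node) or NULL.
#' @param Mb,Mm The corresponding full mass operators (needed when the
#'   matching shape is given).
#' @return Fraction in [0, 1].
#' @export
out_of_plane_fraction <- function(shape_bending = NULL, shape_membrane = NULL,
                                  Mb = NULL, Mm = NULL) {
  total <- 0; transverse <- 0
  if (!is.null(shape_bending)) {
    if (is.null(Mb)) stop("Mb is required with a bending shape")
    total <- total + as.numeric(shape_bending %*% (Mb %*% shape_bending))
    wz <- numeric(length(shape_bending))
    wi <- seq(1L, length(shape_bending), by = 3L)
    wz[wi] <- shape_bending[wi]
    transverse <- transverse + as.numeric(wz %*% (Mb %*% wz))
  }
  if (!is.null(shape_membrane)) {
    if (is.null(Mm)) stop("Mm is required with a membrane shape")
    total <- total + as.numeric(shape_membrane %*% (Mm %*% shape_membrane))
  }
  if (total <= 0) stop("zero total modal mass")
  transverse / total
}

# unique undirected edges of the triangulation
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  unique(e)
}

#' Count same-sign displacement lobes of a transverse field
#'
#' Nodes with |w| below \code{eps} x max|w| form the nodal band; the
#' remaining nodes are partitioned into connected components of the mesh
#' adjacency graph restricted to edges joining nodes of equal sign. One
#' lobe is a septal tilt, two a C-shape, three an S-shape. Nodal lines are
#' traced through the sign-crossing points interpolated on mesh edges
#' (chained triangle-wise); the principal axis of each line gives its
#' orientation: a line running along x (anteroposterior) separates lobes
#' vertically.
#'
#' @param mesh A \code{septum_mesh}.
#' @param w Nodal transverse displacement (length n_nodes).
#' @param eps Relative nodal-band threshold in (0, 0.1), default 0.02.
#' @param ignore_nodes Nodes excluded from the nodal-line fit (defaults to
#'   the fixed bony boundary, which is identically zero).
#' @return List with \code{count}, \code{orientation}
#'   (\code{"anteroposterior"}, \code{"cephalocaudal"}, \code{"mixed"} or
#'   \code{"none"}), and \code{component_sizes}.
#' @export
count_sign_regions <- function(mesh, w, eps = 0.02, ignore_nodes = NULL) {
  if (length(w) != nrow(mesh$nodes)) stop("w must have one value per node")
  wmax <- max(abs(w))
  if (wmax == 0) stop("all-zero transverse field")
  if (eps <= 0 || eps >= 0.1) stop("eps must lie in (0, 0.1)")
  if (is.null(ignore_nodes))
    ignore_nodes <- unlist(mesh$node_sets[intersect(.bony_labels, names(mesh$node_sets))],
                           use.names = FALSE)
  band <- abs(w) < eps * wmax
  sgn <- sign(w)
  ed <- mesh_edges(mesh)

  keep <- !band
  same <- keep[ed[, 1]] & keep[ed[, 2]] & sgn[ed[, 1]] == sgn[ed[, 2]]
  g <- igraph::graph_from_edgelist(ed[same, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$nodes) - igraph::vcount(g)))
  comp <- igraph::components(g)
  memb <- comp$membership[which(keep)]
  sizes <- sort(table(memb), decreasing = TRUE)
  count <- length(sizes)

  # nodal-line orientation from sign-crossing edges: each edge whose
  # endpoints carry opposite signs contributes its interpolated zero
  # crossing; crossings sharing a triangle are chained into lines and each
  # line's principal axis is classified
  orientation <- "none"
  if (count >= 2) {
    cross <- which(w[ed[, 1]] * w[ed[, 2]] < 0 &
                     !(ed[, 1] %in% ignore_nodes) & !(ed[, 2] %in% ignore_nodes))
    if (length(cross) >= 2) {
      a <- ed[cross, 1]; b <- ed[cross, 2]
      tfrac <- w[a] / (w[a] - w[b])
      pts <- mesh$nodes[a, , drop = FALSE] +
        tfrac * (mesh$nodes[b, , drop = FALSE] - mesh$nodes[a, , drop = FALSE])
      ekey <- paste(pmin(a, b), pmax(a, b))
      tr <- mesh$triangles
      glue <- NULL
      for (side in list(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])) {
        k <- match(paste(pmin(side[, 1], side[, 2]), pmax(side[, 1], side[, 2])), ekey)
        glue <- cbind(glue, k)
      }
      pairs <- NULL
      for (cols in list(c(1, 2), c(2, 3), c(1, 3))) {
        p <- glue[, cols, drop = FALSE]
        pairs <- rbind(pairs, p[stats::complete.cases(p), , drop = FALSE])
      }
      gb <- igraph::make_empty_graph(n = length(cross), directed = FALSE)
      if (!is.null(pairs) && nrow(pairs)) gb <- igraph::add_edges(gb, t(pairs))
      cb <- igraph::components(gb)
      dirs <- character(0)
      for (cc in seq_len(cb$no)) {
        idx <- which(cb$membership == cc)
        if (length(idx) < 3) next
        ev <- eigen(stats::cov(pts[idx, , drop = FALSE]), symmetric = TRUE)$vectors[, 1]
        dirs <- c(dirs, if (abs(ev[1]) >= abs(ev[2])) "anteroposterior" else "cephalocaudal")
      }
      if (length(dirs)) {
        u <- unique(dirs)
        orientation <- if (length(u) == 1) u else "mixed"
      }
    }
  }
  list(count = count, orientation = orientation,
       component_sizes = as.integer(sizes))
}

# per-element modal von Mises stress field (arbitrary modal amplitude)
modal_von_mises <- function(mesh, material, shape, family) {
  ne <- nrow(mesh$triangles)
  vm <- numeric(ne)
  if (family == "membrane") {
    D <- plane_stress_D(material)
    for (e in seq_len(ne)) {
      tr <- mesh$triangles[e, ]
      s <- as.numeric(D %*% cst_B(mesh$nodes[tr, , drop = FALSE]) %*%
                        shape[membrane_dofs(tr)])
      vm[e] <- sqrt(max(0, s[1]^2 - s[1] * s[2] + s[2]^2 + 3 * s[3]^2))
    }
  } else {
    nu <- material$nu
    for (e in seq_len(ne)) {
      tr <- mesh$triangles[e, ]
      xy <- mesh$nodes[tr, , drop = FALSE]
      t_e <- mesh$thickness[e]
      Db <- flexural_rigidity(material, t_e) *
        matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
      kap <- as.numeric(dkt_B(xy, 1 / 3, 1 / 3) %*% shape[bending_dofs(tr)])
      m <- as.numeric(Db %*% kap)          # moments per unit length
      s <- 6 * m / t_e^2                   # surface stresses at z = t/2
      vm[e] <- sqrt(max(0, s[1]^2 - s[1] * s[2] + s[2]^2 + 3 * s[3]^2))
    }
  }
  vm
}

#' Classify a single mode into the deviation-type taxonomy
#'
#' A mode whose out-of-plane modal-mass fraction falls below \code{tau} is
#' an in-plane ("dash") mode with no resultant deformation shape. Otherwise
#' the count of same-sign transverse lobes maps to the clinical taxonomy:
#' 1 lobe = septal tilt (I), 2 = C-shape (II), 3 = S-shape (III); counts
#' above 3 are reported as III with a warning (the clinical taxonomy stops
#' at the S-shape). Modal von Mises stress (surface stress for bending
#' modes, membrane stress for in-plane modes; arbitrary amplitude, only
#' locations and rankings are meaningful) is summarized per landmark
#' region.
#'
#' @param shape Full shape vector in the family's DOF layout.
#' @param family \code{"bending"} or \code{"membrane"}.
#' @param mesh A \code{septum_mesh}.
#' @param regions A \code{landmark_regions} (or NULL to skip hotspots).
#' @param material A \code{septum_material}.
#' @param Mb,Mm Full mass operators (for the out-of-plane test).
#' @param tau In-plane threshold on the out-of-plane fraction (default 0.1).
#' @param eps Nodal-band threshold for lobe counting (default 0.02).
#' @return A list: \code{type} ("I", "II", "III" or "-"),
#'   \code{type_numeric} (1/2/3/0), \code{out_of_plane_fraction},
#'   \code{sign_region_count}, \code{orientation}, \code{hotspots}
#'   (data.frame ranked by peak von Mises), \code{max_element}.
#' @export
classify_mode <- function(shape, family, mesh, regions, material,
                          Mb = NULL, Mm = NULL, tau = 0.1, eps = 0.02) {
  frac <- if (family == "bending")
    out_of_plane_fraction(shape_bending = shape, Mb = Mb)
  else out_of_plane_fraction(shape_membrane = shape, Mm = Mm)

  if (frac < tau) {
    type <- "-"; tn <- 0L; count <- NA_integer_; orient <- "none"
  } else {
    wi <- seq(1L, 3L * nrow(mesh$nodes), by = 3L)
    sr <- count_sign_regions(mesh, shape[wi], eps = eps)
    count <- sr$count; orient <- sr$orientation
    if (count > 3)
      warning("mode shows ", count, " lobes; reported as type III ",
              "(taxonomy stops at the S-shape)")
    type <- c("I", "II", "III")[min(count, 3L)]
    tn <- min(count, 3L)
  }

  vm <- modal_von_mises(mesh, material, shape, family)
  hotspots <- NULL; max_el <- which.max(vm)
  if (!is.null(regions)) {
    peak <- vapply(regions, function(els) max(vm[els]), numeric(1))
    containing <- names(regions)[vapply(regions, function(els) max_el %in% els, logical(1))]
    hotspots <- data.frame(landmark = names(regions), peak_von_mises = unname(peak),
                           contains_global_max = names(regions) %in% containing,
                           stringsAsFactors = FALSE)
    hotspots <- hotspots[order(-hotspots$peak_von_mises), ]
    rownames(hotspots) <- NULL
  }
  list(type = type, type_numeric = tn, out_of_plane_fraction = frac,
       sign_region_count = count, orientation = orient,
       hotspots = hotspots, max_element = max_el)
}

#' Classify every mode of a merged mode set
#'
#' @param modes A \code{mode_set} (typically from [merge_and_sort()]).
#' @param mesh A \code{septum_mesh}.
#' @param regions A \code{landmark_regions} or NULL.
#' @param material A \code{septum_material}.
#' @param Mb,Mm Full bending/membrane mass operators.
#' @inheritParams classify_mode
#' @return A \code{mode_classification} data.frame with one row per mode
#'   (columns \code{mode}, \code{frequency_hz}, \code{family},
#'   \code{out_of_plane_fraction}, \code{type}, \code{type_numeric},
#'   \code{sign_regions}, \code{orientation}, \code{top_landmark}), with
#'   per-mode hotspot tables in \code{attr(, "hotspots")} and type counts
#'   in \code{attr(, "summary")}.
#' @export
classify_modeset <- function(modes, mesh, regions, material,
                             Mb, Mm, tau = 0.1, eps = 0.02) {
  stopifnot(inherits(modes, "mode_set"))
  n <- length(modes$frequency)
  if (!n) stop("empty mode set")
  rows <- vector("list", n); hs <- vector("list", n)
  for (k in seq_len(n)) {
    cl <- classify_mode(modes$shapes[[k]], modes$family[k], mesh, regions,
                        material, Mb = Mb, Mm = Mm, tau = tau, eps = eps)
    rows[[k]] <- data.frame(
      mode = k, frequency_hz = modes$frequency[k], family = modes$family[k],
      out_of_plane_fraction = cl$out_of_plane_fraction,
      type = cl$type, type_numeric = cl$type_numeric,
      sign_regions = ifelse(is.na(cl$sign_region_count), NA_integer_, cl$sign_region_count),
      orientation = cl$orientation,
      top_landmark = if (!is.null(cl$hotspots)) cl$hotspots$landmark[1] else NA_character_,
      stringsAsFactors = FALSE)
    hs[[k]] <- cl$hotspots
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mode_classification", class(out))
  attr(out, "hotspots") <- hs
  attr(out, "summary") <- table(factor(out$type, levels = c("I", "II", "III", "-")))
  out
}

#' @export
print.mode_classification <- function(x, ...) {
  df <- as.data.frame(x)
  df$frequency_hz <- round(df$frequency_hz, 1)
  df$out_of_plane_fraction <- round(df$out_of_plane_fraction, 3)
  print(df)
  cat("\nType counts:\n")
  print(attr(x, "summary"))
  invisible(x)
}

#' Clinical summary of a deviation type
#'
#' Static reference text associating each deviation type with its typical
#' dislocation sites and the surgical corrective procedures discussed for
#' it. Informational only; the package makes no surgical recommendation.
#'
#' @param type "I", "II", "III" or "-".
#' @return List with \code{pattern}, \code{dislocation_sites},
#'   \code{procedures}.
#' @export
deviation_type_info <- function(type = c("I", "II", "III", "-")) {
  type <- match.arg(type)
  info <- list(
    "I" = list(
      pattern = "Septal tilt: the septum deviates in one piece.",
      dislocation_sites = c("vomer-ethmoidal cartilage junction (buckling)",
                            "inferior edge off the vomerine groove",
                            "ANS attachment may remain intact"),
      procedures = c("submucous resection", "septal reset to the ANS",
                     "possible septal extension grafts for tip support")),
    "II" = list(
      pattern = "C-shape: a single stress line breaks the septum into two overlapping pieces.",
      dislocation_sites = c("vomer-ethmoidal cartilage junction (buckling)",
                            "inferior edge off the vomerine groove",
                            "single septal fracture site",
                            "ANS attachment may remain intact"),
      procedures = c("septal reset to the ANS", "submucous resection",
                     "spreader grafts buttressing the fracture",
                     "possible septal extension grafts")),
    "III" = list(
      pattern = "S-shape: two stress lines shorten the septum into at least three overlapping pieces (septal concertina).",
      dislocation_sites = c("vomer-ethmoidal cartilage junction (buckling)",
                            "inferior edge off the vomerine groove",
                            "fracture in up to two sites",
                            "ANS attachment may remain intact"),
      procedures = c("septal reset to the ANS", "submucous resection",
                     "longer spreader grafts bracing both fracture sites",
                     "septal extension grafts restoring lost support")),
    "-" = list(
      pattern = "In-plane vibration: no resultant out-of-plane deformation shape.",
      dislocation_sites = character(0),
      procedures = character(0)))
  info[[type]]
}
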