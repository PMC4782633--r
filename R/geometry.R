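#' Default dimensions of the idealized septum midplane (mm)
#'
#' Only the nasal-bone overlap length is anchored to a measured value
#' (14 mm, within the normal 3--15 mm range); the remaining dimensions are
#' documented surrogate defaults for a normal adult quadrangular cartilage
#' and are fully tunable.
#'
#' @return Named list of dimensions in millimetres:
#'   \describe{
#'     \item{inferior_length}{length of the inferior fixed edge (vomerine
#'       groove + maxillary/hard-palate crest), mm.}
#'     \item{posterior_height}{height of the posterior fixed edge against the
#'       perpendicular plate of the ethmoid, mm.}
#'     \item{caudal_length}{length of the free caudal edge from the anterior
#'       nasal spine (ANS) to the anterior septal angle (ASA, "tip"), mm.}
#'     \item{caudal_tilt_deg}{posterior lean of the caudal edge from the
#'       vertical, degrees.}
#'     \item{nasal_bone_overlap}{length of the dorsal edge overlapped (and
#'       fixed) by the nasal bones, mm; must lie in [3, 15].}
#'     \item{vomer_fraction}{fraction of the inferior edge seated in the
#'       vomerine groove (posterior part); the rest is hard palate.}
#'   }
#' @export
#' @examples
#' default_septum_dims()
default_septum_dims <- function() {
  list(
    inferior_length   = 32,
    posterior_height  = 22,
    caudal_length     = 20,
    caudal_tilt_deg   = 10,
    nasal_bone_overlap = 14,
    vomer_fraction    = 0.6
  )
}

#' Construct the parametric idealized septum outline
#'
#' Builds the labelled planar polygon of the cartilage midplane. The
#' coordinate frame is anatomical: x runs posterior to anterior
#' (anteroposterior axis), y runs inferior to superior (cephalocaudal axis),
#' both in millimetres. Counter-clockwise vertex order. The six boundary
#' labels are \code{vomer}, \code{hard_palate} (inferior, fixed),
#' \code{ethmoid} (posterior, fixed), \code{nasal_bone} (posterior dorsal,
#' fixed), \code{dorsal_free} and \code{caudal_free} (free edges). The ASA
#' ("tip") is the dorsal/caudal free-edge junction; the ANS is the
#' anterior end of the inferior edge.
#'
#' @param dims Named list as from [default_septum_dims()]; missing entries
#'   take the defaults.
#' @return A \code{septum_outline} object: \code{vertices} (n x 2 matrix,
#'   mm, counter-clockwise), \code{edge_labels} (label of segment i ->
#'   i+1, cyclic), \code{tip_index}, \code{ans_index}, \code{tip_point},
#'   \code{ans_point}, \code{nasal_bone_overlap}, \code{dims}.
#' @export
#' @examples
#' out <- build_idealized_outline()
#' out$nasal_bone_overlap
build_idealized_outline <- function(dims = list()) {
  d <- utils::modifyList(default_septum_dims(), dims)
  num <- vapply(d, is.numeric, logical(1))
  if (!all(num)) stop("all dimensions must be numeric")
  if (any(unlist(d[names(d) != "caudal_tilt_deg"]) <= 0))
    stop("geometry error: all dimensions must be positive")
  if (d$nasal_bone_overlap < 3 || d$nasal_bone_overlap > 15)
    stop("geometry error: nasal_bone_overlap must lie within 3-15 mm (got ",
         d$nasal_bone_overlap, " mm)")
  if (d$vomer_fraction <= 0 || d$vomer_fraction >= 1)
    stop("geometry error: vomer_fraction must be in (0, 1)")

  L <- d$inferior_length
  H <- d$posterior_height
  alpha <- d$caudal_tilt_deg * pi / 180
  p0  <- c(0, 0)                                   # posterior-inferior corner
  vsp <- c(d$vomer_fraction * L, 0)                # vomer / hard-palate split
  ans <- c(L, 0)
  tip <- ans + d$caudal_length * c(-sin(alpha), cos(alpha))
  p3  <- c(0, H)                                   # posterior-superior corner

  # dorsal edge runs tip -> p3 (counter-clockwise); the posterior
  # `nasal_bone_overlap` mm of it are under the nasal bones
  dors <- p3 - tip
  dorsal_len <- sqrt(sum(dors^2))
  if (d$nasal_bone_overlap >= dorsal_len)
    stop("geometry error: nasal_bone_overlap (", d$nasal_bone_overlap,
         " mm) exceeds the dorsal edge length (", round(dorsal_len, 2), " mm)")
  nb_split <- p3 - dors / dorsal_len * d$nasal_bone_overlap

  vertices <- rbind(p0, vsp, ans, tip, nb_split, p3)
  rownames(vertices) <- NULL
  edge_labels <- c("vomer", "hard_palate", "caudal_free",
                   "dorsal_free", "nasal_bone", "ethmoid")

  out <- structure(list(
    vertices = vertices,
    edge_labels = edge_labels,
    tip_index = 4L, ans_index = 3L,
    tip_point = tip, ans_point = ans,
    nasal_bone_overlap = d$nasal_bone_overlap,
    dims = d
  ), class = "septum_outline")
  validate_outline(out)
  out
}

validate_outline <- function(out) {
  v <- out$vertices
  if (polygon_area(v) <= 0)
    stop("geometry error: outline polygon is degenerate or clockwise")
  if (!polygon_is_simple(v))
    stop("geometry error: outline polygon is self-intersecting")
  if (length(out$edge_labels) != nrow(v))
    stop("geometry error: one label per boundary segment is required")
  invisible(out)
}

#' @export
print.septum_outline <- function(x, ...) {
  cat("Septum midplane outline:", nrow(x$vertices), "vertices,",
      sprintf("area %.1f mm^2,", polygon_area(x$vertices)),
      "nasal-bone overlap", x$nasal_bone_overlap, "mm\n")
  cat("  labels:", paste(unique(x$edge_labels), collapse = ", "), "\n")
  invisible(x)
}

# mapping of boundary labels onto the four macro-sides of the transfinite
# patch (counter-clockwise: bottom, right, top, left)
.side_of_label <- c(
  vomer = "bottom", hard_palate = "bottom",
  caudal_free = "right",
  dorsal_free = "top", nasal_bone = "top",
  ethmoid = "left",
  ss_edge = NA  # fixtures handle their own meshing
)

# split the outline into the four macro-side polylines, each a list with
# points (in bottom->top / left->right parameter direction), cumulative
# normalized arclength of its own vertices, and per-subsegment labels
outline_sides <- function(out) {
  n <- nrow(out$vertices)
  side <- unname(.side_of_label[out$edge_labels])
  if (anyNA(side)) stop("outline has labels without a macro-side assignment")
  segs <- split(seq_len(n), factor(side, levels = c("bottom", "right", "top", "left")))
  if (any(lengths(segs) == 0))
    stop("outline must contain all four macro-sides (inferior, caudal, dorsal, posterior)")
  # segments within a side must be consecutive along the polygon
  grab <- function(idx, reverse = FALSE) {
    idx <- sort(idx)
    pts <- out$vertices[c(idx, idx[length(idx)] %% n + 1L), , drop = FALSE]
    labs <- out$edge_labels[idx]
    if (reverse) {
      pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      labs <- rev(labs)
    }
    seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    s <- c(0, cumsum(seglen))
    list(points = pts, s = s / s[length(s)], length = s[length(s)], labels = labs)
  }
  # counter-clockwise order is bottom, right, top(reversed), left(reversed)
  list(
    bottom = grab(segs$bottom),
    right  = grab(segs$right),
    top    = grab(segs$top, reverse = TRUE),   # reversed: posterior corner -> tip
    left   = grab(segs$left, reverse = TRUE)   # reversed: inferior -> superior
  )
}

# sample a side polyline at normalized arclength parameters ts (0..1)
sample_side <- function(side, ts) {
  pts <- side$points; s <- side$s
  idx <- findInterval(ts, s, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx >= length(s)] <- length(s) - 1L
  w <- (ts - s[idx]) / (s[idx + 1L] - s[idx])
  pts[idx, , drop = FALSE] * (1 - w) + pts[idx + 1L, , drop = FALSE] * w
}

# label of the sub-segment of `side` containing parameter t (midpoint-safe)
side_label_at <- function(side, t) {
  k <- findInterval(t, side$s, rightmost.closed = TRUE)
  k <- min(max(k, 1L), length(side$labels))
  side$labels[k]
}

# uniform 0..1 parameters merged with the side's own vertex positions so
# every outline vertex becomes a mesh node (exact area conservation)
side_params <- function(n, breakpoints) {
  ts <- seq(0, 1, length.out = n + 1L)
  bp <- breakpoints[breakpoints > 1e-12 & breakpoints < 1 - 1e-12]
  for (b in bp) {
    j <- which.min(abs(ts - b))
    if (j == 1L) j <- 2L
    if (j == length(ts)) j <- length(ts) - 1L
    ts[j] <- b                       # snap the nearest interior parameter
  }
  sort(ts)
}

#' Mesh the septum outline with linear triangles
#'
#' Triangulates the midplane by a transfinite (Coons-patch) map over the
#' outline's four macro-sides. Boundary sample points always include the
#' outline's own vertices, so the mesh boundary is a refinement of the
#' outline polygon and the meshed area equals the polygon area to round-off.
#' Output coordinates are in metres (SI); the outline is in millimetres.
#'
#' @param outline A \code{septum_outline}.
#' @param target_edge_length Target element edge length in metres
#'   (default 2 mm).
#' @param thickness Uniform plate thickness in metres (default 2 mm); a
#'   per-element field can be attached afterwards (see
#'   [thickness_field()]).
#' @return A \code{septum_mesh}: \code{nodes} (n x 2, m),
#'   \code{triangles} (m x 3, 1-based, counter-clockwise),
#'   \code{node_sets} (named list incl. \code{tip} and \code{ans}),
#'   \code{boundary_edges} (data.frame \code{n1}, \code{n2}, \code{label},
#'   counter-clockwise), \code{thickness} (per element, m),
#'   \code{outline}.
#' @export
#' @examples
#' msh <- mesh_outline(build_idealized_outline(), target_edge_length = 4e-3)
#' nrow(msh$nodes)
mesh_outline <- function(outline, target_edge_length = 2e-3, thickness = 2e-3) {
  stopifnot(inherits(outline, "septum_outline"))
  if (target_edge_length <= 0) stop("target_edge_length must be positive")
  if (thickness <= 0) stop("thickness must be positive")
  sides <- outline_sides(outline)
  h_mm <- target_edge_length * 1e3

  nx <- max(2L, ceiling(max(sides$bottom$length, sides$top$length) / h_mm))
  ny <- max(2L, ceiling(max(sides$left$length, sides$right$length) / h_mm))

  ts_x <- side_params(nx, sort(unique(c(sides$bottom$s, sides$top$s))))
  ts_y <- side_params(ny, sort(unique(c(sides$left$s, sides$right$s))))
  nx <- length(ts_x) - 1L; ny <- length(ts_y) - 1L

  sB <- sample_side(sides$bottom, ts_x)
  sT <- sample_side(sides$top, ts_x)
  sL <- sample_side(sides$left, ts_y)
  sR <- sample_side(sides$right, ts_y)
  p00 <- sB[1, ]; p10 <- sB[nx + 1L, ]; p01 <- sT[1, ]; p11 <- sT[nx + 1L, ]

  nodes <- matrix(0, (nx + 1L) * (ny + 1L), 2)
  id <- function(i, j) (j - 1L) * (nx + 1L) + i       # i: 1..nx+1, j: 1..ny+1
  for (j in seq_len(ny + 1L)) {
    eta <- ts_y[j]
    for (i in seq_len(nx + 1L)) {
      xi <- ts_x[i]
      nodes[id(i, j), ] <-
        (1 - eta) * sB[i, ] + eta * sT[i, ] +
        (1 - xi) * sL[j, ] + xi * sR[j, ] -
        ((1 - xi) * (1 - eta) * p00 + xi * (1 - eta) * p10 +
           xi * eta * p11 + (1 - xi) * eta * p01)
    }
  }
  nodes <- nodes * 1e-3                                # mm -> m (SI)

  tris <- matrix(0L, 2L * nx * ny, 3)
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      a <- id(i, j); b <- id(i + 1L, j); c <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
      # split along the shorter diagonal for better-conditioned elements
      if (sum((nodes[a, ] - nodes[c, ])^2) <= sum((nodes[b, ] - nodes[d, ])^2)) {
        t1 <- c(a, b, c); t2 <- c(a, c, d)
      } else {
        t1 <- c(a, b, d); t2 <- c(b, c, d)
      }
      tris[k + 1L, ] <- t1; tris[k + 2L, ] <- t2; k <- k + 2L
    }
  }
  areas <- apply(tris, 1, function(tr) tri_area(nodes[tr, ]))
  if (any(areas <= 0)) {
    bad <- which(areas <= 0)[1]
    ctr <- colMeans(nodes[tris[bad, ], ]) * 1e3
    stop(sprintf(paste0("meshing failure: inverted element near (%.1f, %.1f) mm; ",
                        "the outline is too distorted for a transfinite mesh"),
                 ctr[1], ctr[2]))
  }

  # boundary node sets per label (counter-clockwise boundary walk)
  node_sets <- list()
  add_set <- function(sets, lab, idx) { sets[[lab]] <- sort(unique(c(sets[[lab]], idx))); sets }
  walk <- list(
    bottom = list(side = sides$bottom, ids = vapply(seq_len(nx + 1L), function(i) id(i, 1L), 1L), ts = ts_x),
    right  = list(side = sides$right,  ids = vapply(seq_len(ny + 1L), function(j) id(nx + 1L, j), 1L), ts = ts_y),
    top    = list(side = sides$top,    ids = vapply(seq_len(nx + 1L), function(i) id(i, ny + 1L), 1L), ts = ts_x),
    left   = list(side = sides$left,   ids = vapply(seq_len(ny + 1L), function(j) id(1L, j), 1L), ts = ts_y)
  )
  be_n1 <- integer(0); be_n2 <- integer(0); be_lab <- character(0)
  for (w in walk) {
    nseg <- length(w$ids) - 1L
    for (s in seq_len(nseg)) {
      lab <- side_label_at(w$side, (w$ts[s] + w$ts[s + 1L]) / 2)
      node_sets <- add_set(node_sets, lab, w$ids[c(s, s + 1L)])
      be_n1 <- c(be_n1, w$ids[s]); be_n2 <- c(be_n2, w$ids[s + 1L]); be_lab <- c(be_lab, lab)
    }
  }
  # counter-clockwise orientation: bottom and right walks already run ccw;
  # top and left walks run in +parameter direction which is ccw-reversed
  flip <- rep(c(FALSE, FALSE, TRUE, TRUE), times = vapply(walk, function(w) length(w$ids) - 1L, 1L))
  tmp <- be_n1[flip]; be_n1[flip] <- be_n2[flip]; be_n2[flip] <- tmp

  node_sets$tip <- id(nx + 1L, ny + 1L)
  node_sets$ans <- id(nx + 1L, 1L)

  structure(list(
    nodes = nodes,
    triangles = tris,
    node_sets = node_sets,
    boundary_edges = data.frame(n1 = be_n1, n2 = be_n2, label = be_lab,
                                stringsAsFactors = FALSE),
    thickness = rep(thickness, nrow(tris)),
    outline = outline
  ), class = "septum_mesh")
}

#' @export
print.septum_mesh <- function(x, ...) {
  cat("Septum mesh:", nrow(x$nodes), "nodes,", nrow(x$triangles), "triangles,",
      sprintf("area %.2f mm^2,", mesh_area(x) * 1e6),
      sprintf("mean thickness %.2f mm\n", mean(x$thickness) * 1e3))
  invisible(x)
}

#' Total meshed area (m^2)
#' @param mesh A \code{septum_mesh}.
#' @return Sum of triangle areas in square metres.
#' @export
mesh_area <- function(mesh) {
  sum(apply(mesh$triangles, 1, function(tr) tri_area(mesh$nodes[tr, ])))
}

# per-element centroids (n_elem x 2, m)
element_centroids <- function(mesh) {
  t(apply(mesh$triangles, 1, function(tr) colMeans(mesh$nodes[tr, ])))
}

#' Anatomical landmark regions of the meshed septum
#'
#' Collects, for each of the four landmarks discussed in the septal-fracture
#' literature, the mesh elements whose centroid lies within \code{radius} of
#' the landmark: \code{ANS} (anterior nasal spine, a point), \code{BC_junction}
#' (anterior end of the nasal-bone overlap, where the cartilage loses bony
#' support), \code{VEJ} (vomer-ethmoidal cartilage junction, the
#' posterior-inferior corner) and \code{vomerine_groove} (the whole vomer
#' segment of the inferior edge, distance to the segment).
#'
#' @param mesh A \code{septum_mesh} built from a septum outline.
#' @param radius Capture radius in metres (default 3 mm).
#' @return A \code{landmark_regions} object: named list of integer element
#'   index vectors.
#' @export
landmark_regions <- function(mesh, radius = 3e-3) {
  if (radius <= 0) stop("radius must be positive")
  out <- mesh$outline
  if (is.null(out)) stop("mesh carries no outline; landmarks are undefined")
  cen <- element_centroids(mesh)

  pt_region <- function(p_mm) {
    p <- p_mm * 1e-3
    which(sqrt((cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2) <= radius)
  }
  # BC junction: anterior end of the nasal-bone segment along the dorsum
  labs <- out$edge_labels
  nb <- which(labs == "nasal_bone")
  nbv <- out$vertices[nb[1], ]          # segment start = anterior end (ccw: tip->p3 direction)
  # vomerine groove: distance to the vomer sub-segments
  vom <- which(labs == "vomer")
  seg_dist <- function(p, a, b) {
    ab <- b - a; t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  nv <- nrow(out$vertices)
  groove_d <- apply(cen, 1, function(p) {
    min(vapply(vom, function(i) {
      seg_dist(p, out$vertices[i, ] * 1e-3, out$vertices[i %% nv + 1L, ] * 1e-3)
    }, numeric(1)))
  })
  regions <- list(
    ANS = pt_region(out$ans_point),
    BC_junction = pt_region(nbv),
    VEJ = pt_region(out$vertices[1, ]),
    vomerine_groove = which(groove_d <= radius)
  )
  empty <- names(regions)[lengths(regions) == 0]
  if (length(empty))
    stop("landmark radius too small: empty region(s) ",
         paste(empty, collapse = ", "))
  structure(regions, class = "landmark_regions")
}
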