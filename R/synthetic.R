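#' Specification of patient-like geometry and thickness perturbations
#'
#' Seeded low-order harmonic perturbations standing in for a CT-derived
#' patient-specific septum: a smooth radial displacement of the outline and
#' a smooth spatially varying thickness field. Harmonic (rather than
#' arbitrary-noise) perturbation keeps outlines simple and meshes
#' well-conditioned.
#'
#' @param boundary_amplitude Outline displacement amplitude as a fraction
#'   of the mean outline radius, in [0, 0.5) (default 0.05).
#' @param thickness_amplitude Thickness variation amplitude as a fraction
#'   of the 2 mm base thickness, in [0, 0.5) (default 0.25).
#' @param n_harmonics Number of low-order harmonic terms (default 3).
#' @param seed Integer seed; a fixed seed gives bit-reproducible output.
#' @return A \code{perturbation_spec} list.
#' @export
perturbation_spec <- function(boundary_amplitude = 0.05,
                              thickness_amplitude = 0.25,
                              n_harmonics = 3, seed = 1) {
  if (boundary_amplitude < 0 || boundary_amplitude >= 0.5)
    stop("boundary_amplitude must lie in [0, 0.5)")
  if (thickness_amplitude < 0 || thickness_amplitude >= 0.5)
    stop("thickness_amplitude must lie in [0, 0.5)")
  if (n_harmonics < 1) stop("n_harmonics must be at least 1")
  structure(list(boundary_amplitude = boundary_amplitude,
                 thickness_amplitude = thickness_amplitude,
                 n_harmonics = as.integer(n_harmonics),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

# subdivide every outline segment into pieces of at most `h` mm, keeping
# labels and tracking the tip/ANS vertex indices
densify_outline <- function(out, h = 2) {
  v <- out$vertices; n <- nrow(v)
  newv <- NULL; newlab <- character(0)
  tip_i <- ans_i <- NA_integer_
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[i %% n + 1L, ]
    if (i == out$tip_index) tip_i <- nrow(newv %||% matrix(0, 0, 2)) + 1L
    if (i == out$ans_index) ans_i <- nrow(newv %||% matrix(0, 0, 2)) + 1L
    k <- max(1L, ceiling(sqrt(sum((b - a)^2)) / h))
    ts <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    pts <- outer(1 - ts, a) + outer(ts, b)
    newv <- rbind(newv, pts)
    newlab <- c(newlab, rep(out$edge_labels[i], k))
  }
  out2 <- out
  out2$vertices <- newv
  out2$edge_labels <- newlab
  out2$tip_index <- tip_i; out2$ans_index <- ans_i
  out2
}

#' Smooth random perturbation of the septum outline
#'
#' Displaces the (densified) outline vertices radially about the polygon
#' centroid by a seeded low-order harmonic function of the polar angle,
#' normalized so that no vertex moves further than
#' \code{boundary_amplitude} x mean outline radius. Edge labels and the
#' tip/ANS points move with their segments; if the perturbed polygon
#' self-intersects the amplitude is halved and retried before failing.
#'
#' @param outline A \code{septum_outline}.
#' @param spec A [perturbation_spec()].
#' @return A perturbed \code{septum_outline} (identical input is returned
#'   when the amplitude is zero).
#' @export
perturb_outline <- function(outline, spec) {
  stopifnot(inherits(outline, "septum_outline"), inherits(spec, "perturbation_spec"))
  if (spec$boundary_amplitude == 0) return(outline)
  dens <- densify_outline(outline)
  v <- dens$vertices
  ctr <- colMeans(v)
  rad <- sqrt(rowSums(sweep(v, 2, ctr)^2))
  rbar <- mean(rad)
  theta <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
  nh <- spec$n_harmonics
  co <- with_local_seed(spec$seed, list(a = stats::runif(nh, -1, 1),
                                        ph = stats::runif(nh, 0, 2 * pi)))
  g <- rowSums(vapply(seq_len(nh), function(j) co$a[j] * cos(j * theta + co$ph[j]),
                      numeric(nrow(v)))) / sum(abs(co$a))   # sup|g| <= 1
  unit <- sweep(v, 2, ctr) / rad

  amp <- spec$boundary_amplitude
  for (try in 1:4) {
    v2 <- v + (amp * rbar * g) * unit
    if (polygon_is_simple(v2) && polygon_area(v2) > 0) {
      dens$vertices <- v2
      dens$tip_point <- v2[dens$tip_index, ]
      dens$ans_point <- v2[dens$ans_index, ]
      return(dens)
    }
    amp <- amp / 2
  }
  stop("outline perturbation produced a self-intersecting polygon even ",
       "after damping; reduce boundary_amplitude")
}

#' Smooth spatially varying thickness field
#'
#' Per-element thickness t(x, y) = base x (1 + a g(x, y)) where g is a
#' seeded sum of low-order harmonics over the mesh bounding box, re-centred
#' so the mean thickness equals \code{base} exactly and scaled so the field
#' stays within base x (1 +/- thickness_amplitude).
#'
#' @param mesh A \code{septum_mesh}.
#' @param spec A [perturbation_spec()].
#' @param base Base thickness in metres (default 2 mm).
#' @return Numeric per-element thickness vector (m).
#' @export
thickness_field <- function(mesh, spec, base = 2e-3) {
  stopifnot(inherits(spec, "perturbation_spec"))
  ne <- nrow(mesh$triangles)
  if (spec$thickness_amplitude == 0) return(rep(base, ne))
  cen <- element_centroids(mesh)
  xr <- range(cen[, 1]); yr <- range(cen[, 2])
  xt <- (cen[, 1] - xr[1]) / diff(xr); yt <- (cen[, 2] - yr[1]) / diff(yr)
  nh <- spec$n_harmonics
  co <- with_local_seed(spec$seed + 1L, list(
    a = stats::runif(nh, -1, 1), b = stats::runif(nh, -1, 1),
    ph = stats::runif(nh, 0, 2 * pi), ps = stats::runif(nh, 0, 2 * pi)))
  g <- numeric(ne)
  for (j in seq_len(nh))
    g <- g + co$a[j] * cos(j * pi * xt + co$ph[j]) + co$b[j] * cos(j * pi * yt + co$ps[j])
  g <- g - mean(g)
  m <- max(abs(g))
  if (m > 0) g <- g / m
  base * (1 + spec$thickness_amplitude * g)
}

# structured rectangular mesh with all-around "ss_edge" node set; used by
# the analytic validation fixtures
rect_mesh <- function(a, b, nx, ny, thickness = 2e-3) {
  xs <- seq(0, a, length.out = nx + 1L)
  ys <- seq(0, b, length.out = ny + 1L)
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  dimnames(nodes) <- NULL
  tris <- matrix(0L, 2L * nx * ny, 3); k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    aa <- id(i, j); bb <- id(i + 1L, j); cc <- id(i + 1L, j + 1L); dd <- id(i, j + 1L)
    tris[k + 1L, ] <- c(aa, bb, cc); tris[k + 2L, ] <- c(aa, cc, dd); k <- k + 2L
  }
  boundary <- sort(unique(c(id(seq_len(nx + 1L), 1L), id(seq_len(nx + 1L), ny + 1L),
                            id(1L, seq_len(ny + 1L)), id(nx + 1L, seq_len(ny + 1L)))))
  structure(list(
    nodes = nodes, triangles = tris,
    node_sets = list(ss_edge = boundary,
                     tip = id(nx + 1L, ny + 1L), ans = id(nx + 1L, 1L)),
    boundary_edges = data.frame(n1 = integer(0), n2 = integer(0),
                                label = character(0), stringsAsFactors = FALSE),
    thickness = rep(thickness, nrow(tris)),
    outline = NULL
  ), class = "septum_mesh")
}

#' Simply supported rectangular plate fixture with closed-form frequencies
#'
#' Validation fixture for the bending solver: a structured mesh of an
#' a x b Kirchhoff plate, simply supported on all edges, together with the
#' closed-form natural frequencies
#' f_mn = (pi/2) (m^2/a^2 + n^2/b^2) sqrt(D / (rho t)) for m, n <= 3.
#'
#' @param a,b Plate side lengths, m.
#' @param material A \code{septum_material}.
#' @param t Plate thickness, m.
#' @param bc Boundary condition; only \code{"simply_supported"}.
#' @param target_edge_length Mesh resolution, m (default a/12).
#' @return List with \code{mesh} (a \code{septum_mesh} whose boundary node
#'   set is \code{ss_edge}) and \code{analytic} (data.frame \code{m},
#'   \code{n}, \code{frequency_hz}, sorted ascending).
#' @export
#' @examples
#' fx <- rectangular_plate_fixture(0.03, 0.03, cartilage_material(), 2e-3)
#' head(fx$analytic)
rectangular_plate_fixture <- function(a, b, material, t,
                                      bc = "simply_supported",
                                      target_edge_length = a / 12) {
  if (bc != "simply_supported")
    stop("unsupported boundary condition: ", bc)
  if (any(c(a, b, t) <= 0)) stop("plate dimensions must be positive")
  nx <- max(4L, ceiling(a / target_edge_length))
  ny <- max(4L, ceiling(b / target_edge_length))
  mesh <- rect_mesh(a, b, nx, ny, thickness = t)
  D <- flexural_rigidity(material, t)
  grid <- expand.grid(m = 1:3, n = 1:3)
  grid$frequency_hz <- (pi / 2) * (grid$m^2 / a^2 + grid$n^2 / b^2) *
    sqrt(D / (material$rho * t))
  grid <- grid[order(grid$frequency_hz), ]
  rownames(grid) <- NULL
  list(mesh = mesh, analytic = grid)
}
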