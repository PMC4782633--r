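# shared fixtures, memoised so expensive runs happen once per test session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_material <- function() cartilage_material()

# full pipeline run at the default (frozen) configuration
default_run <- function(tip = "spring", load = "couple") {
  cached(paste("run", tip, load),
         run_pipeline(run_config(tip = tip, load = load)))
}

# coarse septum mesh for cheap unit tests
coarse_mesh <- function(h = 2.5e-3) {
  cached(paste("mesh", h), mesh_outline(build_idealized_outline(), h))
}

coarse_system <- function(tip = "spring", h = 2.5e-3) {
  cached(paste("sys", tip, h), {
    spr <- if (tip == "spring") tip_spring(20e3) else NULL
    assemble_system(coarse_mesh(h), default_material(), spr)
  })
}

# axis-aligned rectangular outline carrying the four macro-side labels;
# used for analytic load/area oracles
rect_outline <- function(w = 30, h = 20) {
  out <- structure(list(
    vertices = rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)),
    edge_labels = c("vomer", "caudal_free", "dorsal_free", "ethmoid"),
    tip_index = 3L, ans_index = 2L,
    tip_point = c(w, h), ans_point = c(w, 0),
    nasal_bone_overlap = 14,
    dims = list()
  ), class = "septum_outline")
  out
}

# a two-element unit-square toy mesh on four nodes
toy_mesh <- function(thickness = 2e-3) {
  structure(list(
    nodes = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) * 1e-2,
    triangles = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
    node_sets = list(vomer = c(1L, 2L), tip = 3L, ans = 2L),
    boundary_edges = data.frame(n1 = c(1L, 2L, 3L, 4L), n2 = c(2L, 3L, 4L, 1L),
                                label = c("vomer", "caudal_free", "dorsal_free", "ethmoid"),
                                stringsAsFactors = FALSE),
    thickness = rep(thickness, 2),
    outline = NULL
  ), class = "septum_mesh")
}

# independent flood-fill labelling of same-sign components (oracle for
# count_sign_regions; no graph library, plain breadth-first search)
brute_force_sign_components <- function(mesh, w, eps) {
  band <- abs(w) < eps * max(abs(w))
  sgn <- sign(w)
  tr <- mesh$triangles
  adj <- vector("list", nrow(mesh$nodes))
  add <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b); adj[[b]] <<- c(adj[[b]], a)
  }
  for (e in seq_len(nrow(tr))) {
    add(tr[e, 1], tr[e, 2]); add(tr[e, 2], tr[e, 3]); add(tr[e, 3], tr[e, 1])
  }
  seen <- band            # band nodes are never visited
  count <- 0L
  for (s in seq_len(nrow(mesh$nodes))) {
    if (seen[s]) next
    count <- count + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (!seen[u] && sgn[u] == sgn[v]) {
          seen[u] <- TRUE; queue <- c(queue, u)
        }
      }
    }
  }
  count
}

# smooth pseudo-random nodal field over a mesh (low-order sines)
random_smooth_field <- function(mesh, seed) {
  set.seed(seed)
  xr <- range(mesh$nodes[, 1]); yr <- range(mesh$nodes[, 2])
  xt <- (mesh$nodes[, 1] - xr[1]) / diff(xr)
  yt <- (mesh$nodes[, 2] - yr[1]) / diff(yr)
  f <- numeric(nrow(mesh$nodes))
  for (j in 1:3)
    f <- f + stats::runif(1, -1, 1) * sin(j * pi * xt + stats::runif(1, 0, pi)) *
      sin(j * pi * yt + stats::runif(1, 0, pi))
  f
}
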