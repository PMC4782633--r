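#' Write a mesh with attached fields as a legacy-ASCII VTK unstructured grid
#'
#' Minimal writer for the legacy VTK file format (DATASET UNSTRUCTURED_GRID,
#' triangle cells): point scalars/vectors and cell scalars, suitable for
#' ParaView. The planar mesh is embedded at z = 0.
#'
#' @param mesh A \code{septum_mesh}.
#' @param path Output file path (conventionally \code{.vtk}).
#' @param point_data Named list of per-node fields: numeric vectors
#'   (scalars) or n x 3 matrices (vectors).
#' @param cell_data Named list of per-element numeric vectors.
#' @param title Dataset title line.
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list(),
                      title = "septamodal mesh") {
  np <- nrow(mesh$nodes); ne <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl(title)
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", np, " double")
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  wl("CELLS ", ne, " ", 4L * ne)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  wl("CELL_TYPES ", ne)
  writeLines(rep("5", ne), con)
  if (length(point_data)) {
    wl("POINT_DATA ", np)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        wl("VECTORS ", nm, " double")
        writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2],
                           if (ncol(v) > 2) v[, 3] else 0), con)
      } else {
        wl("SCALARS ", nm, " double 1")
        wl("LOOKUP_TABLE default")
        writeLines(sprintf("%.9g", v), con)
      }
    }
  }
  if (length(cell_data)) {
    wl("CELL_DATA ", ne)
    for (nm in names(cell_data)) {
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Default pipeline configuration
#'
#' All physical defaults are the model constants of the study conditions:
#' E = 5 MPa, nu = 0.32, rho = 2000 kg/m^3, thickness 2 mm, tip spring
#' 20 kN/m, couple force 1 N per axis, edge pressure 2000 Pa, nasal-bone
#' overlap 14 mm, 10 modes.
#'
#' @param ... Named overrides of any configuration entry (nested lists such
#'   as \code{geometry} are merged element-wise).
#' @return A \code{run_config} list.
#' @export
#' @examples
#' cfg <- run_config(tip = "free", mesh_size_mm = 2)
run_config <- function(...) {
  cfg <- list(
    geometry = default_septum_dims(),
    material = list(E_mpa = 5, nu = 0.32, rho = 2000),
    thickness_mm = 2,
    tip = "spring",              # "spring" or "free"
    spring_k = 20e3,             # N/m per axis
    load = "couple",             # "couple" or "pressure"
    force_n = 1,
    pressure_pa = 2000,
    n_modes = 10L,
    mesh_size_mm = 1.5,
    tau = 0.1,                   # in-plane (dash) threshold
    eps = 0.02,                  # nodal-band threshold
    landmark_radius_mm = 3,
    perturb = NULL,              # list(boundary_amplitude, thickness_amplitude, n_harmonics)
    seed = 1L,
    output_dir = NULL
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, over, keep.null = TRUE)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!cfg$tip %in% c("spring", "free")) stop("tip must be 'spring' or 'free'")
  if (!cfg$load %in% c("couple", "pressure")) stop("load must be 'couple' or 'pressure'")
  with(cfg, {
    if (material$E_mpa <= 0 || material$rho <= 0) stop("material constants must be positive")
    if (material$nu < 0 || material$nu >= 0.5) stop("nu must lie in [0, 0.5)")
    if (thickness_mm <= 0 || mesh_size_mm <= 0) stop("thickness and mesh size must be positive")
    if (spring_k < 0 || force_n < 0 || pressure_pa < 0) stop("load/spring magnitudes must be non-negative")
    if (n_modes < 1) stop("n_modes must be at least 1")
  })
  # canonical storage types so YAML round-trips are identical()
  for (nm in c("thickness_mm", "spring_k", "force_n", "pressure_pa",
               "mesh_size_mm", "tau", "eps", "landmark_radius_mm"))
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  cfg$geometry <- lapply(cfg$geometry, as.numeric)
  cfg$material <- lapply(cfg$material, as.numeric)
  if (!is.null(cfg$perturb)) cfg$perturb <- lapply(cfg$perturb, as.numeric)
  cfg$n_modes <- as.integer(cfg$n_modes)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' The on-disk representation round-trips losslessly through
#' [read_run_config()].
#'
#' @param cfg A \code{run_config}.
#' @param path YAML file path.
#' @return The path ([write_run_config()]) or the configuration
#'   ([read_run_config()]).
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Fingerprint of a run configuration (for output provenance)
#' @param cfg A \code{run_config}.
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(cfg) {
  config_fingerprint(paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n"))
}
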