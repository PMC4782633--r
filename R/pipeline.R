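#' Run the full septum modal pipeline
#'
#' Executes geometry -> meshing -> assembly -> static preload -> geometric
#' stiffness -> eigen extraction -> classification for one configuration,
#' optionally writing CSV tables, VTK fields, the configuration and a log
#' to \code{output_dir}. With \code{config$perturb} set, the idealized
#' outline and uniform thickness are replaced by the seeded patient-like
#' perturbation before meshing.
#'
#' @param config A [run_config()].
#' @param output_dir Output directory (overrides \code{config$output_dir});
#'   \code{NULL} writes nothing.
#' @return A \code{septum_run}: \code{config}, \code{hash}, \code{mesh},
#'   \code{system}, \code{preload} (membrane state), \code{modes},
#'   \code{classification}, \code{log}, \code{files}.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(mesh_size_mm = 3))
#' run$classification$type
#' }
run_pipeline <- function(config = run_config(), output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  output_dir <- output_dir %||% config$output_dir
  hash <- config_hash(config)
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  say("config hash ", hash, ", seed ", config$seed)

  stage <- "geometry"
  res <- tryCatch({
    outline <- build_idealized_outline(config$geometry)
    pspec <- NULL
    if (!is.null(config$perturb)) {
      pspec <- do.call(perturbation_spec,
                       c(config$perturb, list(seed = config$seed)))
      outline <- perturb_outline(outline, pspec)
      say("outline perturbed (amplitude ", pspec$boundary_amplitude, ")")
    }
    mesh <- mesh_outline(outline, config$mesh_size_mm * 1e-3,
                         thickness = config$thickness_mm * 1e-3)
    if (!is.null(pspec))
      mesh$thickness <- thickness_field(mesh, pspec, base = config$thickness_mm * 1e-3)
    say("mesh: ", nrow(mesh$nodes), " nodes, ", nrow(mesh$triangles),
        " elements, area ", sprintf("%.1f", mesh_area(mesh) * 1e6), " mm^2")

    stage <- "assembly"
    material <- cartilage_material(E = config$material$E_mpa * 1e6,
                                   nu = config$material$nu,
                                   rho = config$material$rho)
    spring <- if (config$tip == "spring") tip_spring(config$spring_k) else NULL
    sys <- assemble_system(mesh, material, spring)

    stage <- "preload"
    lc <- load_case(if (config$load == "couple") "anteroposterior_couple"
                    else "dorsal_caudal_pressure",
                    force_magnitude = config$force_n,
                    pressure_magnitude = config$pressure_pa)
    f <- build_load_vector(mesh, lc)
    state <- solve_membrane_static(sys, f)
    say("static preload (", config$load, "): residual ",
        format(state$residual, digits = 3), ", max von Mises ",
        sprintf("%.3g", max(state$von_mises)), " Pa")
    Kg <- assemble_geometric_stiffness(mesh, state)

    stage <- "modal"
    nb <- config$n_modes + 2L   # headroom so the merge always has n modes
    bending <- solve_bending_modes(sys, Kg, nb)
    membrane <- solve_membrane_modes(sys, nb)
    modes <- merge_and_sort(bending, membrane, config$n_modes)
    rb <- mode_residuals(bending, sys$Kb + Kg, sys$Mb, sys$free_b)
    say("modes: f1 = ", sprintf("%.1f", modes$frequency[1]), " Hz (fundamental), f",
        config$n_modes, " = ", sprintf("%.1f", modes$frequency[config$n_modes]),
        " Hz; max bending eigen-residual ", format(max(rb), digits = 3))

    stage <- "classify"
    regions <- landmark_regions(mesh, config$landmark_radius_mm * 1e-3)
    cls <- withCallingHandlers(
      classify_modeset(modes, mesh, regions, material, sys$Mb, sys$Mm,
                       tau = config$tau, eps = config$eps),
      warning = function(w) { say("warning: ", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    say("types: ", paste(cls$type, collapse = " "))
    list(mesh = mesh, system = sys, preload = state, modes = modes,
         classification = cls)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "' (config ", hash, "): ",
         conditionMessage(e), call. = FALSE)
  })

  say("done in ", sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))), " s")
  run <- structure(c(list(config = config, hash = hash), res,
                     list(log = log, files = character(0))),
                   class = "septum_run")
  if (!is.null(output_dir)) run <- write_run_artifacts(run, output_dir)
  run
}

#' @export
print.septum_run <- function(x, ...) {
  cat("Septum pipeline run ", x$hash, " (tip: ", x$config$tip,
      ", load: ", x$config$load, ")\n", sep = "")
  print(x$classification)
  invisible(x)
}

# write the CSV / VTK / YAML / log artifacts of a finished run
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  cls <- as.data.frame(run$classification)
  cls$config_hash <- run$hash
  utils::write.csv(cls, p("classification.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mode = seq_along(run$modes$frequency),
                              frequency_hz = run$modes$frequency,
                              family = run$modes$family,
                              config_hash = run$hash),
                   p("frequencies.csv"), row.names = FALSE)
  write_run_config(run$config, p("config.yaml"))
  wi <- seq(1L, 3L * nrow(run$mesh$nodes), by = 3L)
  pd <- list(preload_displacement = cbind(run$preload$u[seq(1L, length(run$preload$u), 2L)],
                                          run$preload$u[seq(2L, length(run$preload$u), 2L)],
                                          0))
  for (k in seq_along(run$modes$frequency)) {
    pd[[sprintf("mode_%02d_w", k)]] <-
      if (run$modes$family[k] == "bending") run$modes$shapes[[k]][wi]
      else numeric(nrow(run$mesh$nodes))
  }
  write_vtk(run$mesh, p("modes.vtk"), point_data = pd,
            cell_data = list(preload_von_mises = run$preload$von_mises,
                             thickness = run$mesh$thickness),
            title = paste("septamodal run", run$hash))
  writeLines(run$log, p("run.log"))
  run$files <- c(p("classification.csv"), p("frequencies.csv"),
                 p("config.yaml"), p("modes.vtk"), p("run.log"))
  run
}

#' Compare the deviation-type sequences of several runs
#'
#' Aligns the per-mode type labels of two or more finished runs (equal
#' mode counts required) and counts the modes on which all runs agree,
#' mirroring the side-by-side columns of the published modal-shape table.
#'
#' @param runs List of \code{septum_run} objects (or bare
#'   \code{mode_classification} tables); names become column names.
#' @return A \code{data.frame} with one row per mode and one type column
#'   per run, plus attribute \code{agreement} (number of modes with
#'   identical labels across all runs).
#' @export
compare_models <- function(runs) {
  if (length(runs) < 2) stop("need at least two runs to compare")
  cls <- lapply(runs, function(r)
    if (inherits(r, "septum_run")) r$classification else r)
  nm <- vapply(cls, nrow, integer(1))
  if (length(unique(nm)) != 1)
    stop("runs have different mode counts: ", paste(nm, collapse = ", "))
  labels <- names(runs) %||% paste0("run", seq_along(runs))
  labels[labels == ""] <- paste0("run", which(labels == ""))
  out <- data.frame(mode = seq_len(nm[1]))
  for (i in seq_along(cls)) out[[labels[i]]] <- cls[[i]]$type
  agree <- sum(apply(out[, -1, drop = FALSE], 1, function(r) length(unique(r)) == 1))
  attr(out, "agreement") <- agree
  out
}
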