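#' Scenario configuration
#'
#' Collects every knob of a full run: phantom, grid, array, steering,
#' solver, correction scheme, nonlinearity and skull-base handling.  The
#' configuration hash is recorded in the result provenance so a run can be
#' reproduced bit-exactly.
#'
#' @param phantom a [phantom_spec()], a [ct_volume()], or `NULL` for a
#'   water-only run.
#' @param grid_dims,spacing_mm simulation grid size and spacing.
#' @param grid_origin_mm coordinate (mm) of voxel (1,1,1); default centres
#'   the grid on the geometric focus.
#' @param duration_us simulated time (microseconds).
#' @param array_args arguments for [generate_array()].
#' @param surface_diameter Huygens reduction-surface diameter (m).
#' @param steering_mm steering offset from the geometric focus
#'   (mm; x lateral, z axial).
#' @param solver `"acoustic"` or `"elastic"`.
#' @param correction aberration-correction scheme.
#' @param nonlinear logical.
#' @param remove_skull_base logical; zero the skull below
#'   `skull_base_plane_mm` before map building.
#' @param skull_base_plane_mm cutting plane (mm, z); default 9 mm below the
#'   target.
#' @param hu_threshold skull extraction threshold (HU).
#' @param cfl solver CFL number (<= 0.3).
#' @param sensors optional sensor positions (m).
#' @param seed RNG seed for the phantom texture.
#' @return an object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       grid_dims = c(96, 96, 96), spacing_mm = 1,
                       grid_origin_mm = NULL,
                       duration_us = 120,
                       array_args = list(),
                       surface_diameter = 0.11,
                       steering_mm = c(16, 0, 3),
                       solver = c("acoustic", "elastic"),
                       correction = c("none", "phase", "phase_amplitude",
                                      "phase_inverse_amplitude"),
                       nonlinear = FALSE,
                       remove_skull_base = FALSE,
                       skull_base_plane_mm = NULL,
                       hu_threshold = 300, cfl = 0.3,
                       sensors = NULL, seed = 1) {
  solver <- match.arg(solver)
  correction <- match.arg(correction)
  cfg <- list(phantom = phantom, grid_dims = as.integer(grid_dims),
              spacing_mm = spacing_mm, grid_origin_mm = grid_origin_mm,
              duration_us = duration_us,
              array_args = array_args, surface_diameter = surface_diameter,
              steering_mm = as.numeric(steering_mm), solver = solver,
              correction = correction, nonlinear = nonlinear,
              remove_skull_base = remove_skull_base,
              skull_base_plane_mm = skull_base_plane_mm,
              hu_threshold = hu_threshold, cfl = cfl,
              sensors = sensors, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

# stable md5 of a configuration
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(lapply(unclass(cfg), function(x)
    if (is.numeric(x)) signif(x, 12) else x)), f)
  unname(tools::md5sum(f))
}

#' Run a full simulation scenario
#'
#' Orchestrates phantom -> material maps -> array/steering -> (optional
#' aberration correction) -> Huygens surface source -> solver -> beam
#' metrics.  Skull-base removal zeroes the skull voxels below the cutting
#' plane before map building.
#'
#' @param config a [run_config()].
#' @param reference optional reference `sim_result` for the shift metric.
#' @return list with `result` (`sim_result`), `metrics` (data frame),
#'   `config`, `hash`.
#' @export
run_scenario <- function(config, reference = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dims <- config$grid_dims
  spacing <- config$spacing_mm * 1e-3
  grid <- sim_grid(dims, spacing,
                   origin = if (is.null(config$grid_origin_mm)) NULL
                            else config$grid_origin_mm * 1e-3,
                   duration = config$duration_us * 1e-6,
                   cfl = config$cfl %||% 0.3)

  # --- phantom / maps ---
  if (is.null(config$phantom)) {
    maps <- uniform_maps(grid, "water")
  } else {
    ct <- if (inherits(config$phantom, "ct_volume")) config$phantom
    else {
      ph <- config$phantom
      ph$seed <- config$seed
      generate_skull_phantom(ph, dims = dims,
                             spacing_mm = config$spacing_mm,
                             origin_mm = config$grid_origin_mm)
    }
    if (config$remove_skull_base) {
      target_z <- config$steering_mm[3]
      plane <- config$skull_base_plane_mm %||% (target_z - 9)
      zax <- ct$origin[3] + (seq_len(dim(ct$voxels)[3]) - 1) * ct$spacing[3]
      ct$voxels[, , zax < plane] <- 0
    }
    maps <- build_material_maps(ct, config$hu_threshold)
  }

  # --- array, steering, correction ---
  geometry <- do.call(generate_array, config$array_args)
  target <- config$steering_mm * 1e-3
  drives <- steering_phases(geometry, target)
  if (config$correction != "none") {
    corr <- measure_corrections(maps, geometry, target, grid,
                                exterior = TRUE,
                                relay_surface = surface_spec(
                                  config$surface_diameter * 0.9))
    drives <- apply_correction(drives, corr, config$correction)
  }

  # --- Huygens reduction and solve ---
  surf <- project_to_surface(geometry, drives,
                             surface_spec(config$surface_diameter))
  src <- surface_to_time_source(surf, grid, target = target)
  result <- if (config$solver == "acoustic")
    run_acoustic(maps, src, grid,
                 mode = if (config$nonlinear) "nonlinear" else "linear",
                 sensors = config$sensors)
  else
    run_elastic(to_viscoelastic(maps, geometry$f0), src, grid,
                sensors = config$sensors)
  result$provenance$config_hash <- hash
  metrics <- beam_metrics(result, reference = reference, center = target)
  metrics$config_hash <- hash
  list(result = result, metrics = metrics, config = config, hash = hash)
}

#' Compare two simulation runs
#'
#' Normalized peak ratio, signed peak shift and per-threshold volume
#' ratios between two runs on the same grid.
#'
#' @param result_a,result_b `sim_result` objects on the same grid.
#' @param thresholds dB thresholds for the volume ratios.
#' @param axis beam axis for the shift.
#' @return a one-row `data.frame`.
#' @export
compare_runs <- function(result_a, result_b, thresholds = c(-3.5, -7),
                         axis = c(0, 0, 1)) {
  if (!all(result_a$grid$dims == result_b$grid$dims) ||
      result_a$grid$spacing != result_b$grid$spacing)
    stop("runs are on different grids")
  ma <- beam_metrics(result_a, thresholds_fine = thresholds,
                     thresholds_coarse = numeric(0))
  mb <- beam_metrics(result_b, thresholds_fine = thresholds,
                     thresholds_coarse = numeric(0))
  out <- data.frame(peak_ratio = ma$peak_Pa / mb$peak_Pa,
                    shift_mm = as.numeric(peak_shift(result_a, result_b, axis)))
  for (th in thresholds) {
    nm <- sprintf("vol_%gdB_mm3", -th)
    out[[sprintf("vol_%gdB_ratio", -th)]] <- ma[[nm]] / mb[[nm]]
  }
  out
}
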