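#' Measure per-element aberration corrections
#'
#' Simulates a point source at the target through the material maps and
#' extracts the complex received amplitude at the centre of each array
#' element by a least-squares sinusoid fit over the trailing steady-state
#' cycles.  By acoustic reciprocity, conjugating these phases refocuses the
#' array on the target through the aberrator.
#'
#' Element centres must lie inside the simulation grid; for full-scale
#' arrays that do not fit, `exterior = TRUE` records the field on a Huygens
#' hemisphere inside the grid and propagates it analytically through water
#' to the element centres.
#'
#' @param maps a `material_maps` object.
#' @param geometry an [generate_array()] object.
#' @param target point-source position (m), inside the brain region.
#' @param grid a [sim_grid()].
#' @param solver `"acoustic"` (default) or `"elastic"`.
#' @param fit_cycles trailing cycles for the sinusoid fit.
#' @param exterior use the Huygens relay for element centres outside the
#'   grid.
#' @param relay_surface a [surface_spec()] for the relay hemisphere.
#' @return an object of class `correction_set`: `phase` (rad),
#'   `amplitude` (a.u.) per element.
#' @export
measure_corrections <- function(maps, geometry, target, grid,
                                solver = c("acoustic", "elastic"),
                                fit_cycles = 10, exterior = FALSE,
                                relay_surface = surface_spec()) {
  solver <- match.arg(solver)
  f0 <- geometry$f0
  src <- point_time_source(grid, target, S = 1, f0 = f0)
  if (exterior) {
    sensors <- relay_points(relay_surface, maps, grid)
  } else {
    ok <- tryCatch({ pos_to_voxel(grid, geometry$centers); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("element centre outside grid; use exterior = TRUE")
    sensors <- geometry$centers
  }
  res <- if (solver == "acoustic")
    run_acoustic(maps, src, grid, sensors = sensors, record_start = "none")
  else
    run_elastic(to_viscoelastic(maps, f0), src, grid, sensors = sensors,
                record_start = "none")
  ph <- vapply(seq_len(ncol(res$traces)), function(j)
    steady_phasor(res$traces[, j], res$dt, f0, fit_cycles),
    complex(1))
  if (exterior) {
    # water Huygens relay: each sample radiates S = 2 i k p ds outward
    k <- 2 * pi * f0 / maps$constants$c_water
    S <- 2i * k * ph * attr(sensors, "ds")
    ph <- monopole_sum_cpp(sensors, S, geometry$centers, k) / (4 * pi)
  }
  structure(list(phase = Arg(ph), amplitude = Mod(ph), complex = ph,
                 scheme = NULL, f0 = f0, target = target,
                 exterior = exterior),
            class = "correction_set")
}

relay_points <- function(surface, maps, grid) {
  lam <- maps$constants$c_water / 220e3
  h <- lam * surface$spacing_fraction
  n <- max(64, ceiling(2 * pi * surface$radius^2 / h^2))
  i <- seq_len(n)
  cz <- -(i - 0.5) / n
  st <- sqrt(pmax(0, 1 - cz^2))
  phi <- pi * (3 - sqrt(5)) * i
  pts <- surface$radius * cbind(st * cos(phi), st * sin(phi), cz)
  pts <- sweep(pts, 2, surface$center, "+")
  attr(pts, "ds") <- 2 * pi * surface$radius^2 / n
  pts
}

#' Apply an aberration-correction scheme to element drives
#'
#' All schemes conjugate the measured phase; the amplitude rules are:
#' `phase` keeps the input amplitudes; `phase_amplitude` drives each
#' element inversely proportional to its measured amplitude (equalizing
#' per-element contributions at the focus) and excludes elements whose
#' required coefficient exceeds twice the mean; `phase_inverse_amplitude`
#' drives proportionally to the measured amplitude (boosting
#' low-attenuation paths).  Total power `sum |w|^2` is renormalized to the
#' input drive power in every scheme.
#'
#' @param drives input [element_drive()].
#' @param corrections a [measure_corrections()] result.
#' @param scheme one of `"none"`, `"phase"`, `"phase_amplitude"`,
#'   `"phase_inverse_amplitude"`.
#' @param exclusion_factor clipping threshold (x mean coefficient).
#' @return a corrected [element_drive()].
#' @export
apply_correction <- function(drives, corrections,
                             scheme = c("none", "phase", "phase_amplitude",
                                        "phase_inverse_amplitude"),
                             exclusion_factor = 2) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(drives)
  stopifnot(inherits(corrections, "correction_set"),
            length(corrections$phase) == length(drives$weights))
  p_in <- drive_power(drives)
  phase <- -corrections$phase
  excluded <- drives$excluded
  amp <- switch(scheme,
    phase = Mod(drives$weights),
    phase_amplitude = {
      a <- 1 / corrections$amplitude
      a[!is.finite(a)] <- Inf
      excl <- a > exclusion_factor * mean(a[is.finite(a)])
      excluded <- excluded | excl
      a[excluded] <- 0
      a
    },
    phase_inverse_amplitude = corrections$amplitude)
  if (all(amp == 0)) stop("all elements excluded by the clipping rule")
  w <- amp * exp(1i * phase)
  w[excluded] <- 0
  w <- w * sqrt(p_in / sum(Mod(w)^2))
  element_drive(w, excluded)
}
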