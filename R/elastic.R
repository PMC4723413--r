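#' Run the Kelvin-Voigt viscoelastic solver
#'
#' Staggered-grid velocity-stress leapfrog with spectral derivatives and a
#' multi-axis split-field PML.  Shear-mode conversion and shear absorption
#' in the skull are captured through the voxel-wise Lame/viscosity maps;
#' fluid voxels are carried with `mu = 0`.  The scalar pressure recorded in
#' `pmax` is the mean normal stress `-(s_xx + s_yy + s_zz)/3`.
#'
#' @param coeffs a [to_viscoelastic()] object.
#' @param source a `time_source`.
#' @param grid a [sim_grid()]; the elastic CFL default is 0.2 (plain PSTD
#'   without the k-space temporal correction).
#' @param sensors optional sensor positions (m).
#' @param record_start as in [run_acoustic()].
#' @param cfl CFL override (<= 0.3).
#' @param shear_diagnostics compute the final-step Helmholtz split of the
#'   velocity field over solid voxels (shear vs total kinetic energy).
#' @return a `sim_result`.
#' @export
run_elastic <- function(coeffs, source, grid, sensors = NULL,
                        record_start = "crossing", cfl = 0.2,
                        shear_diagnostics = FALSE) {
  stopifnot(inherits(coeffs, "viscoelastic_coefficients"),
            inherits(source, "time_source"), inherits(grid, "sim_grid"))
  lam <- as.numeric(coeffs$lambda); mu <- as.numeric(coeffs$mu)
  chi <- as.numeric(coeffs$chi); eta <- as.numeric(coeffs$eta)
  rho <- as.numeric(coeffs$rho)
  cp <- sqrt((lam + 2 * mu) / rho)
  c_max <- max(cp)
  dt <- cfl * grid$spacing / c_max
  if (dt > source$dt_max) dt <- source$dt_max
  nt <- ceiling(grid$duration / dt)

  rs <- if (identical(record_start, "crossing"))
    ceiling(max(grid$dims) * grid$spacing / min(cp) / dt)
  else if (identical(record_start, "none")) 0L
  else ceiling(as.numeric(record_start) / dt)
  rs <- min(rs, nt - 1L)

  sensor_idx <- integer(0)
  if (!is.null(sensors))
    sensor_idx <- voxel_lin0(grid, pos_to_voxel(grid, sensors))

  squeeze <- function(x) if (length(unique(round(x, 9))) == 1) x[1] else x
  res <- run_elastic_core(
    grid$dims, grid$spacing, dt, as.integer(nt),
    squeeze(lam), squeeze(mu), squeeze(chi), squeeze(eta), squeeze(rho),
    grid$pml_size, grid$pml_alpha, c_max,
    as.integer(source$idx0), Re(source$amp), Im(source$amp),
    source$f0, source$ramp_cycles,
    as.integer(rs), as.integer(sensor_idx), shear_diagnostics,
    if (is.null(source$stop_time)) -1 else source$stop_time)
  res$energy <- numeric(0)
  sim_result(res, grid, dt, nt, solver = "elastic",
             record_start = rs, sensors = sensors,
             source_mask = source$mask_idx0)
}
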