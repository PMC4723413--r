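#' Run the k-space pseudospectral acoustic solver
#'
#' First-order staggered-grid k-space scheme for the coupled momentum /
#' mass-conservation / pressure-closure system on heterogeneous fluid maps,
#' with split-field quartic PML, optional quadratic (B/A) nonlinearity and
#' fractional-Laplacian power-law absorption.  The per-voxel maximum
#' pressure is recorded after a configurable warm-up.
#'
#' @param maps a `material_maps` object (or `uniform_maps()`).
#' @param source a `time_source`.
#' @param grid a [sim_grid()].
#' @param mode `"linear"` or `"nonlinear"`.
#' @param sensors optional n x 3 matrix of sensor positions (m); pressure
#'   time series are recorded there at every step.
#' @param record_start `"crossing"` (default: one domain crossing at the
#'   slowest map speed), `"none"`, or a time in seconds.
#' @param absorption `"auto"` (skip the operator when total attenuation
#'   across the domain is negligible, < 1e-3 Np), `"on"` or `"off"`.
#' @param absorption_power frequency power-law exponent y of the absorption
#'   operator; the prefactor is scaled so absorption at the source frequency
#'   matches the material maps exactly, and the operator's spectral filters
#'   are clamped above three times the carrier wavenumber (the dispersion
#'   coefficient tan(pi y / 2) diverges as y approaches 1, which makes
#'   near-1 exponents unusable with skull-grade absorption).
#' @param c_ref reference speed of the k-space correction; defaults to the
#'   map maximum.
#' @param energy record total acoustic energy per step (diagnostics).
#' @param kspace_correction apply the sinc temporal correction (default).
#'   Disabling it yields the plain PSTD leapfrog update, which shares its
#'   time discretization with the elastic solver (used by the fluid-limit
#'   equivalence checks).
#' @return an object of class `sim_result`: `pmax` (Pa, array), `traces`
#'   (nt x nsensors), `dt`, `nt`, `grid`, `provenance`.
#' @export
run_acoustic <- function(maps, source, grid, mode = c("linear", "nonlinear"),
                         sensors = NULL, record_start = "crossing",
                         absorption = c("auto", "on", "off"),
                         absorption_power = 1.5, c_ref = NULL,
                         energy = FALSE, kspace_correction = TRUE) {
  mode <- match.arg(mode)
  absorption <- match.arg(absorption)
  stopifnot(inherits(source, "time_source"), inherits(grid, "sim_grid"))
  check_maps_grid(maps, grid)

  c0 <- as.numeric(maps$c_p)
  rho0 <- as.numeric(maps$rho)
  c_max <- max(c0)
  if (is.null(c_ref)) c_ref <- c_max
  dt <- grid_dt(grid, c_max)
  if (dt > source$dt_max) dt <- source$dt_max
  nt <- ceiling(grid$duration / dt)

  absorbing <- switch(absorption, on = TRUE, off = FALSE, auto = {
    a_np <- alpha_np_per_m(max(maps$alpha_p), source$f0)
    a_np * max(grid$dims) * grid$spacing > 1e-3
  })
  if (absorbing) {
    ap <- acoustic_absorption_params(maps, source$f0, absorption_power)
    tau <- as.numeric(ap$tau); eta <- as.numeric(ap$eta); ypow <- ap$y
  } else {
    tau <- 0; eta <- 0; ypow <- absorption_power
  }

  rs <- if (identical(record_start, "crossing"))
    ceiling(max(grid$dims) * grid$spacing / min(c0) / dt)
  else if (identical(record_start, "none")) 0L
  else ceiling(as.numeric(record_start) / dt)
  rs <- min(rs, nt - 1L)

  sensor_idx <- integer(0)
  if (!is.null(sensors))
    sensor_idx <- voxel_lin0(grid, pos_to_voxel(grid, sensors))

  # collapse uniform fields to scalars for the core
  squeeze <- function(x) if (length(unique(round(x, 9))) == 1) x[1] else x
  res <- run_acoustic_core(
    grid$dims, grid$spacing, dt, as.integer(nt),
    squeeze(c0), squeeze(rho0), c_ref,
    grid$pml_size, grid$pml_alpha,
    as.integer(source$idx0), Re(source$amp), Im(source$amp),
    source$f0, source$ramp_cycles,
    as.integer(rs), as.integer(sensor_idx),
    mode == "nonlinear", squeeze(as.numeric(maps$BonA)),
    absorbing, squeeze(tau), squeeze(eta), ypow, energy,
    if (is.null(source$stop_time)) -1 else source$stop_time,
    kspace_correction, 3 * 2 * pi * source$f0 / min(c0))

  sim_result(res, grid, dt, nt, solver = "acoustic", mode = mode,
             record_start = rs, sensors = sensors,
             source_mask = source$mask_idx0,
             extra = list(absorbing = absorbing, c_ref = c_ref))
}

check_maps_grid <- function(maps, grid) {
  if (!is.null(dim(maps$c_p)) &&
      !all(dim(maps$c_p) == grid$dims))
    stop("material maps and grid dimensions differ")
  invisible(TRUE)
}

sim_result <- function(core, grid, dt, nt, solver, mode = "linear",
                       record_start = 0, sensors = NULL,
                       source_mask = NULL, extra = list()) {
  pmax <- array(core$pmax, grid$dims)
  prov <- c(list(solver = solver, mode = mode, dt = dt, nt = nt,
                 record_start = record_start,
                 version = as.character(utils::packageVersion("skullwave"))),
            extra)
  structure(list(pmax = pmax, traces = core$traces,
                 p_final = array(core$p_final, grid$dims),
                 energy = core$energy,
                 shear_energy = core$shear_energy,
                 solid_kinetic_energy = core$solid_kinetic_energy,
                 dt = dt, nt = nt, grid = grid, sensors = sensors,
                 source_mask_idx0 = source_mask,
                 provenance = prov),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s/%s, %d steps, dt = %.3g us, peak %.4g Pa\n",
              x$provenance$solver, x$provenance$mode, x$nt, x$dt * 1e6,
              max(x$pmax)))
  invisible(x)
}

#' Plane-wave transmission error of the discretized solver
#'
#' Launches a pseudo-1-D plane wave across a flat interface between two
#' fluids and compares the steady-state pressure transmission coefficient
#' with the analytic impedance result `T = 2 Z2 / (Z1 + Z2)`.  Used for the
#' grid-resolution study: the worst-case water-to-bone interface at 1 mm
#' spacing and 220 kHz.
#'
#' @param c1,rho1 incidence-side speed (m/s) and density (kg/m^3).
#' @param c2,rho2 transmission-side properties.
#' @param spacing grid spacing (m).
#' @param f0 frequency (Hz).
#' @param nx domain length in voxels (5-smooth sizes are fastest).
#' @return list with `T_sim`, `T_analytic`, `rel_error`.
#' @export
measure_plane_wave_transmission <- function(c1, rho1, c2, rho2,
                                            spacing = 1e-3, f0 = 220e3,
                                            nx = 360) {
  nx <- good_grid_size(nx)
  pml <- 10
  i_src <- pml + 20L
  i_int <- as.integer(round(nx * 0.6))
  lam2 <- c2 / f0
  i_sen <- i_int + as.integer(round(4 * lam2 / spacing))
  if (i_sen >= nx - pml - 5)
    stop("interface/sensor would fall inside the PML; increase nx")

  c0 <- rep(c1, nx); c0[i_int:nx] <- c2
  rho <- rep(rho1, nx); rho[i_int:nx] <- rho2
  travel <- (i_int - i_src) * spacing / c1 + (i_sen - i_int) * spacing / c2
  dur <- travel + 30 / f0
  grid <- sim_grid(c(nx, 1, 1), spacing, duration = dur, pml_size = pml)
  maps <- structure(list(c_p = array(c0, c(nx, 1, 1)),
                         rho = array(rho, c(nx, 1, 1)),
                         alpha_p = array(0, c(nx, 1, 1)),
                         BonA = array(0, c(nx, 1, 1))),
                    class = "material_maps")
  src <- raw_time_source(grid, voxel_to_pos(grid, c(i_src, 1, 1)),
                         1 + 0i, f0, ramp_cycles = 3)
  sensor <- voxel_to_pos(grid, c(i_sen, 1, 1))
  run1 <- run_acoustic(maps, src, grid, sensors = sensor,
                       record_start = "none", absorption = "off")
  # reference: homogeneous incidence medium
  maps0 <- maps
  maps0$c_p[] <- c1; maps0$rho[] <- rho1
  run0 <- run_acoustic(maps0, src, grid, sensors = sensor,
                       record_start = "none", absorption = "off")
  a1 <- steady_amplitude(run1$traces[, 1], run1$dt, f0, cycles = 10)
  a0 <- steady_amplitude(run0$traces[, 1], run0$dt, f0, cycles = 10)
  T_sim <- a1 / a0
  T_an <- analytic_transmission(list(c1 = c1, rho1 = rho1,
                                     c2 = c2, rho2 = rho2))$transmission
  list(T_sim = T_sim, T_analytic = T_an,
       rel_error = abs(T_sim - T_an) / T_an)
}

# least-squares sinusoid amplitude over the trailing `cycles` periods
steady_amplitude <- function(trace, dt, f0, cycles = 10) {
  Mod(steady_phasor(trace, dt, f0, cycles))
}

# complex phasor A with p(t) ~ Re(A exp(-i omega t)) over the trailing
# window; an intercept column absorbs any DC offset (1-D continuous-wave
# sources carry a propagating DC step)
steady_phasor <- function(trace, dt, f0, cycles = 10) {
  n <- length(trace)
  m <- min(n, max(16, round(cycles / (f0 * dt))))
  idx <- (n - m + 1):n
  t <- (idx - 1) * dt
  X <- cbind(1, cos(2 * pi * f0 * t), sin(2 * pi * f0 * t))
  cf <- qr.solve(X, trace[idx])
  complex(real = cf[2], imaginary = cf[3])
}

#' Harmonic content of a focal time trace
#'
#' Hann-windowed Fourier amplitudes at the fundamental and second harmonic
#' over the trailing steady-state window (trimmed to an integer number of
#' carrier cycles so a pure tone leaks nothing into the harmonic bin).
#'
#' @param trace pressure time series (Pa).
#' @param dt sample interval (s).
#' @param f0 fundamental frequency (Hz).
#' @param analysis_window window length (s) from the end of the trace; must
#'   cover at least 2 cycles (>= 20 recommended).
#' @return list with `A1`, `A2` (Pa) and `ratio_db` = `20 log10(A2/A1)`.
#' @export
harmonic_spectrum <- function(trace, dt, f0, analysis_window) {
  ncyc <- floor(analysis_window * f0)
  if (ncyc < 2) stop("analysis window shorter than 2 cycles")
  m <- round(ncyc / (f0 * dt))
  if (m > length(trace)) stop("analysis window longer than the trace")
  x <- tail(trace, m)
  t <- (seq_len(m) - 1) * dt
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / m)
  amp_at <- function(f) {
    z <- sum(w * x * exp(-2i * pi * f * t))
    2 * Mod(z) / sum(w)
  }
  A1 <- amp_at(f0); A2 <- amp_at(2 * f0)
  list(A1 = A1, A2 = A2, ratio_db = 20 * log10(A2 / A1))
}
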