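#' Acoustic and viscoelastic material constants
#'
#' Reference values for water, brain and skull bone used by the porosity
#' mapping.  Sound speeds in m/s, absorption in dB MHz^-1 cm^-1 (linear
#' frequency law), densities in kg/m^3.  Skull absorption interpolates
#' between `alpha_min_skull` (dense cortical bone) and `alpha_max_skull`
#' (full porosity) with a square-root porosity law.  Shear-wave properties
#' are tied to the compressional ones by fixed ratios (4/7 for speed,
#' 90/85 for absorption), and the acoustic nonlinearity parameter B/A is
#' 7.1 in tissue/skull and 5.2 in water.
#'
#' @param c_water,c_bone,c_brain compressional sound speeds (m/s).
#' @param alpha_min_skull,alpha_max_skull,alpha_brain,alpha_water absorption
#'   (dB MHz^-1 cm^-1).
#' @param rho_bone,rho_brain,rho_water densities (kg/m^3).
#' @param shear_speed_ratio,shear_absorption_ratio dimensionless ratios
#'   mapping compressional to shear properties inside the skull.
#' @param BonA_tissue,BonA_water nonlinearity parameters.
#' @return an object of class `material_constants`.
#' @export
material_constants <- function(c_water = 1480, c_bone = 3100, c_brain = 1560,
                               alpha_min_skull = 0.64,
                               alpha_max_skull = 25.46,
                               alpha_brain = 0.34, alpha_water = 2.5e-5,
                               rho_bone = 2200, rho_brain = 1030,
                               rho_water = 1000,
                               shear_speed_ratio = 4 / 7,
                               shear_absorption_ratio = 90 / 85,
                               BonA_tissue = 7.1, BonA_water = 5.2) {
  k <- as.list(environment())
  with(k, {
    stopifnot(c_water > 0, c_bone > 0, c_brain > 0,
              rho_bone > 0, rho_brain > 0, rho_water > 0,
              alpha_max_skull >= alpha_min_skull,
              shear_speed_ratio > 0, shear_absorption_ratio > 0)
  })
  structure(k, class = "material_constants")
}

#' Convert Hounsfield units to skull porosity
#'
#' `psi = 1 - H/1000`, clamped to `[0, 1]` so that CT values above 1000 HU
#' (very dense cortical bone) map to zero porosity.
#'
#' @param H Hounsfield units (scalar or array).
#' @return porosity in `[0, 1]`, same shape as `H`.
#' @export
hounsfield_to_porosity <- function(H) {
  if (any(!is.finite(H))) stop("Hounsfield input contains non-finite values")
  pmin(pmax(1 - H / 1000, 0), 1)
}

#' Map porosity to compressional skull properties
#'
#' Linear porosity mixing for sound speed and density between the water and
#' dense-bone endpoints, and a square-root porosity law for absorption.
#'
#' @param psi porosity in `[0, 1]`.
#' @param constants a [material_constants()] object.
#' @return list with `c_p` (m/s), `alpha_p` (dB MHz^-1 cm^-1), `rho` (kg/m^3).
#' @export
porosity_to_properties <- function(psi, constants = material_constants()) {
  if (any(psi < 0 | psi > 1)) stop("porosity must lie in [0, 1]")
  list(c_p = constants$c_water * psi + constants$c_bone * (1 - psi),
       alpha_p = constants$alpha_min_skull +
         (constants$alpha_max_skull - constants$alpha_min_skull) * sqrt(psi),
       rho = constants$rho_water * psi + constants$rho_bone * (1 - psi))
}

#' Shear-wave properties from compressional maps
#'
#' Applies the fixed ratios voxel-wise inside the skull mask; fluid voxels
#' carry zero shear speed and absorption.
#'
#' @param c_p,alpha_p compressional speed and absorption fields.
#' @param skull_mask logical field marking bone voxels.
#' @param constants a [material_constants()] object.
#' @return list with `c_s` (m/s) and `alpha_s` (dB MHz^-1 cm^-1).
#' @export
derive_shear_properties <- function(c_p, alpha_p, skull_mask,
                                    constants = material_constants()) {
  c_s <- ifelse(skull_mask, constants$shear_speed_ratio * c_p, 0)
  a_s <- ifelse(skull_mask, constants$shear_absorption_ratio * alpha_p, 0)
  list(c_s = c_s, alpha_s = a_s)
}

# dB MHz^-1 cm^-1 at a linear frequency law -> Np/m at frequency f0 (Hz)
alpha_np_per_m <- function(alpha_db_mhz_cm, f0) {
  alpha_db_mhz_cm * (f0 / 1e6) * 100 * log(10) / 20
}

#' Build voxel-wise material maps from a CT volume
#'
#' Voxels at or above `skull_hu_threshold` form the skull mask and receive
#' porosity-mapped properties; all other voxels are homogeneous brain tissue
#' (or water, when `background = "water"`).
#'
#' @param ct a [ct_volume] object (Hounsfield units).
#' @param skull_hu_threshold HU threshold for skull extraction.
#' @param constants a [material_constants()] object.
#' @param background `"brain"` or `"water"` for the non-skull region.
#' @return an object of class `material_maps` with per-voxel fields `c_p`,
#'   `c_s`, `alpha_p`, `alpha_s`, `rho`, `BonA` and the logical `skull_mask`.
#' @export
build_material_maps <- function(ct, skull_hu_threshold = 300,
                                constants = material_constants(),
                                background = c("brain", "water")) {
  background <- match.arg(background)
  stopifnot(inherits(ct, "ct_volume"))
  hu <- ct$voxels
  mask <- hu >= skull_hu_threshold
  if (!any(mask))
    warning("skull mask is empty at the requested HU threshold")
  dims <- dim(hu)
  if (background == "brain") {
    c_bg <- constants$c_brain; a_bg <- constants$alpha_brain
    r_bg <- constants$rho_brain; ba_bg <- constants$BonA_tissue
  } else {
    c_bg <- constants$c_water; a_bg <- constants$alpha_water
    r_bg <- constants$rho_water; ba_bg <- constants$BonA_water
  }
  c_p <- array(c_bg, dims); alpha_p <- array(a_bg, dims)
  rho <- array(r_bg, dims); BonA <- array(ba_bg, dims)
  if (any(mask)) {
    psi <- hounsfield_to_porosity(hu[mask])
    pr <- porosity_to_properties(psi, constants)
    c_p[mask] <- pr$c_p; alpha_p[mask] <- pr$alpha_p; rho[mask] <- pr$rho
    BonA[mask] <- constants$BonA_tissue
  }
  sh <- derive_shear_properties(c_p, alpha_p, mask, constants)
  structure(list(c_p = c_p, c_s = array(sh$c_s, dims),
                 alpha_p = alpha_p, alpha_s = array(sh$alpha_s, dims),
                 rho = rho, BonA = BonA, skull_mask = mask,
                 spacing_mm = ct$spacing, origin_mm = ct$origin,
                 constants = constants, background = background,
                 skull_hu_threshold = skull_hu_threshold),
            class = "material_maps")
}

#' Homogeneous material maps
#'
#' Convenience constructor for water-only (or brain-only) runs on a given
#' grid, without a CT volume.
#'
#' @param grid a [sim_grid()].
#' @param medium `"water"` or `"brain"`.
#' @param constants a [material_constants()] object.
#' @return a `material_maps` object.
#' @export
uniform_maps <- function(grid, medium = c("water", "brain"),
                         constants = material_constants()) {
  medium <- match.arg(medium)
  ct <- ct_volume(array(0, grid$dims), spacing = rep(grid$spacing * 1e3, 3),
                  origin = grid$origin * 1e3)
  suppressWarnings(
    build_material_maps(ct, skull_hu_threshold = 1e9, constants = constants,
                        background = if (medium == "water") "water" else "brain"))
}

#' Viscoelastic coefficients for the elastic solver
#'
#' Lame constants from the sound speeds and density (`mu = c_s^2 rho`,
#' `lambda + 2 mu = c_p^2 rho`) and Kelvin-Voigt viscosities from the
#' absorption coefficients (`eta = 2 rho c_s^3 alpha_s / omega^2`,
#' `chi + 2 eta = 2 rho c_p^3 alpha_p / omega^2`, with alpha converted to
#' Np/m at the driving frequency).  The omega^2 factor makes the standard
#' low-loss Kelvin-Voigt relation dimensionally consistent with absorption
#' specified at a single frequency.
#'
#' @param maps a `material_maps` object.
#' @param f0 driving frequency (Hz).
#' @return an object of class `viscoelastic_coefficients` with per-voxel
#'   `lambda`, `mu` (Pa), `chi`, `eta` (Pa s) and `rho` (kg/m^3).
#' @export
to_viscoelastic <- function(maps, f0) {
  stopifnot(inherits(maps, "material_maps"), f0 > 0)
  omega <- 2 * pi * f0
  mu <- maps$c_s^2 * maps$rho
  lambda <- maps$c_p^2 * maps$rho - 2 * mu
  a_s <- alpha_np_per_m(maps$alpha_s, f0)
  a_p <- alpha_np_per_m(maps$alpha_p, f0)
  eta <- 2 * maps$rho * maps$c_s^3 * a_s / omega^2
  chi <- 2 * maps$rho * maps$c_p^3 * a_p / omega^2 - 2 * eta
  if (any(chi < 0) || any(eta < 0))
    stop("negative Kelvin-Voigt viscosity; absorption ratios are unphysical")
  structure(list(lambda = lambda, mu = mu, chi = chi, eta = eta,
                 rho = maps$rho, f0 = f0, spacing_mm = maps$spacing_mm),
            class = "viscoelastic_coefficients")
}

# power-law absorption operator parameters for the acoustic solver:
# alpha0 * omega^y Np/m matching the table value exactly at f0.  tau is
# the coefficient applied to the spectrally filtered rho0 div(u) term
# (div u = -d(rho)/dt / rho0 for the linearized mass balance), eta the
# dispersion-correction coefficient on the density sum.
acoustic_absorption_params <- function(maps, f0, y = 1.5) {
  a_np <- alpha_np_per_m(maps$alpha_p, f0)
  alpha0 <- a_np / (2 * pi * f0)^y
  list(tau = -2 * alpha0 * maps$c_p^(y - 1),
       eta = 2 * alpha0 * maps$c_p^y * tan(pi * y / 2),
       y = y)
}
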