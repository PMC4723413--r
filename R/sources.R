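#' Rayleigh piston field of a single array element
#'
#' Discretized Rayleigh-Sommerfeld integral over a circular piston face:
#' `p(x) = (i omega rho / 2 pi) w * sum exp(i k r)/r dS`, with the face
#' sampled on a cartesian lattice at `>= subsamples_per_wavelength` points
#' per wavelength.  Linear in the complex drive `w` (interpreted as the
#' piston normal velocity, m/s).
#'
#' @param center,normal,radius element centre (m), unit normal, piston
#'   radius (m).
#' @param drive complex element weight.
#' @param points n x 3 matrix of field positions (m).
#' @param medium list with sound speed `c` (m/s) and density `rho` (kg/m^3).
#' @param f0 frequency (Hz).
#' @param subsamples_per_wavelength face sampling density (>= 6).
#' @return complex pressures (Pa) at `points`.
#' @export
rayleigh_piston_field <- function(center, normal, radius, drive, points,
                                  medium = list(c = 1480, rho = 1000),
                                  f0 = 220e3,
                                  subsamples_per_wavelength = 6) {
  points <- matrix(points, ncol = 3)
  k <- 2 * pi * f0 / medium$c
  sub <- piston_face_points(center, normal, radius, medium$c / f0,
                            subsamples_per_wavelength)
  # singularity guard: points must not lie on the piston plane inside the face
  rel <- sweep(points, 2, center, "-")
  zn <- rel %*% normal
  lat <- sqrt(pmax(0, rowSums(rel^2) - zn^2))
  if (any(abs(zn) < 1e-9 & lat <= radius + 1e-9))
    stop("field point lies on the piston face (singular Rayleigh integral)")
  amp <- (1i * 2 * pi * f0 * medium$rho / (2 * pi)) * drive * sub$ds
  amps <- rep(amp, nrow(sub$pts))
  monopole_sum_cpp(sub$pts, amps, points, k)
}

# cartesian sampling of a circular piston face; returns points and the
# per-point area weight ds (m^2)
piston_face_points <- function(center, normal, radius, wavelength,
                               per_wavelength = 6) {
  h <- min(wavelength / per_wavelength, radius / 2.5)
  m <- ceiling(radius / h)
  g <- (-m:m) * h
  gg <- expand.grid(u = g, v = g)
  keep <- gg$u^2 + gg$v^2 <= radius^2
  gg <- gg[keep, , drop = FALSE]
  b <- orthonormal_basis(normal)
  pts <- cbind(center[1] + gg$u * b$e1[1] + gg$v * b$e2[1],
               center[2] + gg$u * b$e1[2] + gg$v * b$e2[2],
               center[3] + gg$u * b$e1[3] + gg$v * b$e2[3])
  # scale the cell area so the sampled area equals the true face area
  list(pts = pts, ds = pi * radius^2 / nrow(pts))
}

orthonormal_basis <- function(n) {
  n <- n / sqrt(sum(n^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Steering phases for a target position
#'
#' Conjugates the water time of flight from each element to the target:
#' with the package's `exp(-i omega t)` phasor convention the emitted phase
#' is `-k (|x_i - target| - R_ref)`, so all element contributions arrive in
#' phase at the target.  Amplitudes are unity.
#'
#' @param geometry an [generate_array()] object.
#' @param target steering target (m), inside the hemisphere.
#' @param c_ref reference sound speed (m/s), water by default.
#' @return an object of class `element_drive` (complex `weights`,
#'   logical `excluded`).
#' @export
steering_phases <- function(geometry, target, c_ref = 1480) {
  target <- as.numeric(target)
  if (sqrt(sum((target - geometry$focus)^2)) >= geometry$hemisphere_radius)
    stop("steering target must lie inside the hemisphere")
  k <- 2 * pi * geometry$f0 / c_ref
  d <- sqrt(rowSums(sweep(geometry$centers, 2, target, "-")^2))
  phase <- -k * (d - geometry$hemisphere_radius)
  element_drive(exp(1i * phase))
}

#' Element drive weights
#' @param weights complex per-element weights.
#' @param excluded logical flags; excluded elements have weight forced to 0.
#' @return object of class `element_drive`.
#' @export
element_drive <- function(weights, excluded = rep(FALSE, length(weights))) {
  stopifnot(all(is.finite(Re(weights))), all(is.finite(Im(weights))),
            length(excluded) == length(weights))
  weights[excluded] <- 0
  structure(list(weights = weights, excluded = excluded),
            class = "element_drive")
}

# total radiated power metric sum |w|^2
drive_power <- function(drive) sum(Mod(drive$weights)^2)

#' Hemispherical Huygens surface specification
#'
#' @param diameter surface diameter (m); 0.11 m emulates a reduction surface
#'   placed close to a ~7 cm cranium.
#' @param spacing_fraction sample spacing as a fraction of the water
#'   wavelength (<= 1/4).
#' @param center centre (m).
#' @param cap_fraction extension of the cap above the equator, as a
#'   fraction of the radius: rays from rim elements to a steered target
#'   cross the surface slightly above the equatorial plane, so a bare
#'   half sphere misses part of the aperture.
#' @return object of class `surface_spec`.
#' @export
surface_spec <- function(diameter = 0.11, spacing_fraction = 1 / 4,
                         center = c(0, 0, 0), cap_fraction = 0.15) {
  stopifnot(diameter > 0, spacing_fraction <= 1 / 4 + 1e-12,
            cap_fraction >= 0, cap_fraction < 1)
  structure(list(radius = diameter / 2, spacing_fraction = spacing_fraction,
                 center = as.numeric(center), cap_fraction = cap_fraction),
            class = "surface_spec")
}

#' Project element fields onto the fictitious Huygens surface
#'
#' Superposes the Rayleigh piston fields of all driven elements at
#' quasi-uniform sample points of the hemispherical reduction surface.
#' In `restrict = TRUE` mode each element only illuminates the samples
#' inside its geometric-optics cross section (the cone from the element
#' aperture toward the focus); the default is unrestricted superposition,
#' which is exact under Huygens' principle.
#'
#' @param geometry an [generate_array()] object.
#' @param drives an [element_drive()] object.
#' @param surface a [surface_spec()].
#' @param medium list with `c` and `rho` of the coupling water.
#' @param restrict logical; apply per-element cross-section restriction.
#' @param focus_hint cone apex for the restriction mode (m).
#' @param subsamples_per_wavelength piston face sampling density.
#' @return an object of class `surface_source`: sample `points` (m),
#'   `normals`, complex `pressure` (Pa), sample area `ds` (m^2) and
#'   provenance fields.
#' @export
project_to_surface <- function(geometry, drives,
                               surface = surface_spec(),
                               medium = list(c = 1480, rho = 1000),
                               restrict = FALSE,
                               focus_hint = geometry$focus,
                               subsamples_per_wavelength = 6) {
  lam <- medium$c / geometry$f0
  h <- lam * surface$spacing_fraction
  cap <- surface$cap_fraction %||% 0
  span <- 1 + cap                       # cz from +cap down to -1
  nsamp <- max(32, ceiling(2 * pi * surface$radius^2 * span / h^2))
  i <- seq_len(nsamp)
  cz <- cap - (i - 0.5) / nsamp * span
  st <- sqrt(pmax(0, 1 - cz^2))
  phi <- pi * (3 - sqrt(5)) * i
  pts <- surface$radius * cbind(st * cos(phi), st * sin(phi), cz)
  pts <- sweep(pts, 2, surface$center, "+")
  normals <- -sweep(pts, 2, surface$center, "-") / surface$radius
  ds <- 2 * pi * surface$radius^2 * span / nsamp
  k <- 2 * pi * geometry$f0 / medium$c

  p <- complex(real = numeric(nsamp), imaginary = numeric(nsamp))
  active <- which(!drives$excluded & Mod(drives$weights) > 0)
  for (e in active) {
    sel <- seq_len(nsamp)
    if (restrict) {
      ec <- geometry$centers[e, ]
      axis <- focus_hint - ec
      dfe <- sqrt(sum(axis^2)); axis <- axis / dfe
      half_angle <- atan((geometry$element_radius + lam / 2) / dfe)
      rel <- sweep(pts, 2, ec, "-")
      proj <- rel %*% axis
      perp <- sqrt(pmax(0, rowSums(rel^2) - proj[, 1]^2))
      sel <- which(proj[, 1] > 0 &
                     atan2(perp, proj[, 1]) <= half_angle)
      if (!length(sel)) next
    }
    p[sel] <- p[sel] + rayleigh_piston_field(
      geometry$centers[e, ], geometry$normals[e, ], geometry$element_radius,
      drives$weights[e], pts[sel, , drop = FALSE], medium, geometry$f0,
      subsamples_per_wavelength)
  }
  structure(list(points = pts, normals = normals, pressure = p, ds = ds,
                 radius = surface$radius, center = surface$center,
                 f0 = geometry$f0, medium = medium,
                 restricted = restrict),
            class = "surface_source")
}

#' Convert a surface source to a time-domain solver source
#'
#' Each surface sample becomes an additive mass-rate monopole at its nearest
#' grid voxel, with complex amplitude `-2 ds / (c0 dx^3) * p_s` chosen so
#' that the forward-radiated field of the discrete monopole set reproduces
#' the Rayleigh (first-kind) integral of the surface pressure.  The drive is
#' `|p| sin(2 pi f0 t + arg p)` with a raised-cosine onset.
#'
#' @param src a [project_to_surface()] result.
#' @param grid a [sim_grid()].
#' @param ramp_cycles onset length in carrier cycles.
#' @param smooth spatially band-limit the injected distribution.  Off by
#'   default: the dense surface shell already injects a propagating-band
#'   spectrum, and the filter's tail truncation measurably perturbs the
#'   beam wings (a few percent on iso-dB volumes).  Compact sources
#'   ([point_time_source()]) keep smoothing on.
#' @param target steering target for the snap-phase re-projection.
#' @return an object of class `time_source`.
#' @export
surface_to_time_source <- function(src, grid, ramp_cycles = 3,
                                   smooth = FALSE, target = NULL) {
  dx <- grid$spacing
  if (dx > src$medium$c / src$f0 / 2)
    stop("grid too coarse for the surface-source frequency")
  amp <- -2 * src$ds / (src$medium$c * dx^3) * src$pressure
  # snapping a sample to its voxel centre moves it by up to half a voxel
  # diagonal; re-project the phase along the local propagation direction
  # (toward the steering target) so the snapped monopoles stay coherent
  if (is.null(target)) target <- src$center
  ijk <- pos_to_voxel(grid, src$points)
  vpos <- voxel_to_pos(grid, ijk)
  d <- sweep(src$points, 2, target, "-")
  d <- -d / sqrt(rowSums(d^2))           # unit vector sample -> target
  delta <- rowSums((vpos - src$points) * d)
  k <- 2 * pi * src$f0 / src$medium$c
  # Rayleigh obliquity: each sample radiates with the cosine between the
  # inward surface normal and the direction toward the focus
  obliq <- pmax(0, rowSums(src$normals * d))
  amp <- amp * exp(1i * k * delta) * obliq
  raw_time_source(grid, vpos, amp, src$f0, ramp_cycles,
                  smooth = smooth, c_source = src$medium$c)
}

#' Point monopole time source
#'
#' Injects a monopole whose complex far-field is
#' `S exp(i k r) / (4 pi r)`; used by calibration tests and as the point
#' source of the aberration-correction measurement.
#'
#' @param grid a [sim_grid()].
#' @param position source position (m).
#' @param S complex monopole strength (Pa m).
#' @param f0 frequency (Hz).
#' @param ramp_cycles onset cycles.
#' @return a `time_source`.
#' @export
point_time_source <- function(grid, position, S = 1, f0 = 220e3,
                              ramp_cycles = 3, smooth = TRUE,
                              c_source = 1480) {
  omega <- 2 * pi * f0
  raw_time_source(grid, matrix(position, ncol = 3),
                  1i * S / (omega * grid$spacing^3), f0, ramp_cycles,
                  smooth = smooth, c_source = c_source)
}

# raw injection amplitudes at voxel positions (for tests and aperture
# discretizations): amps are complex mass-rate amplitudes per voxel
raw_time_source <- function(grid, positions, amps, f0, ramp_cycles = 3,
                            smooth = TRUE, c_source = 1480) {
  ijk <- pos_to_voxel(grid, positions)
  lin <- voxel_lin0(grid, ijk)
  agg <- rowsum(cbind(Re(amps), Im(amps)), lin)
  idx0 <- as.integer(rownames(agg))
  src <- structure(list(idx0 = idx0,
                        amp = complex(real = agg[, 1], imaginary = agg[, 2]),
                        f0 = f0, ramp_cycles = ramp_cycles,
                        dt_max = 1 / (10 * f0),
                        mask_idx0 = dilate_idx0(idx0, grid, 2L)),
                   class = "time_source")
  if (smooth) smooth_time_source(src, grid, c_source) else src
}

# indices (0-based) of the source voxels dilated by `r` voxels per axis;
# used to exclude the source shell's near field from beam metrics
dilate_idx0 <- function(idx0, grid, r = 2L) {
  d <- grid$dims
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  off <- expand.grid(a = -r:r, b = -r:r, c = -r:r)
  out <- unlist(lapply(seq_len(nrow(off)), function(m) {
    ii <- pmin(pmax(i + off$a[m], 0L), d[1] - 1L)
    jj <- pmin(pmax(j + off$b[m], 0L), d[2] - 1L)
    kk <- pmin(pmax(k + off$c[m], 0L), d[3] - 1L)
    ii + d[1] * (jj + d[2] * kk)
  }))
  sort(unique(as.integer(out)))
}

# Band-limit the injected source distribution: a voxel delta excites the
# whole discrete spectrum, and content far above the carrier wavenumber
# only produces truncation ringing around the source.  A radial raised-
# cosine low-pass (flat through ~1.25 k0, zero by the axis Nyquist) leaves
# the radiated field untouched and removes the ringing.
smooth_time_source <- function(src, grid, c_source = 1480) {
  dims <- grid$dims
  n <- prod(dims)
  dx <- grid$spacing
  k0 <- 2 * pi * src$f0 / c_source
  knyq <- pi / dx
  a <- min(1.25 * k0, 0.7 * knyq)
  b <- min(max(2.5 * k0, 1.3 * a), knyq)
  f <- array(0i, dims)
  f[src$idx0 + 1] <- src$amp
  F <- array(fft3_cpp(as.vector(f), dims, FALSE), dims)
  kax <- function(nn) {
    i <- 0:(nn - 1)
    fr <- ifelse(i <= nn / 2, i, i - nn)
    2 * pi * fr / (nn * dx)
  }
  kk <- sqrt(outer(outer(kax(dims[1])^2, kax(dims[2])^2, "+"),
                   kax(dims[3])^2, "+"))
  W <- ifelse(kk <= a, 1,
              ifelse(kk >= b, 0, 0.5 * (1 + cos(pi * (kk - a) / (b - a)))))
  f <- array(fft3_cpp(as.vector(F * W), dims, TRUE), dims)
  keep <- which(Mod(f) > 1e-5 * max(Mod(f)))
  src$idx0 <- as.integer(keep - 1L)
  src$amp <- f[keep]
  src
}

# monopole-set time source from strengths S_j (field = sum S_j e^{ikr}/4 pi r);
# `target` enables snap-phase re-projection toward a focal point
monopole_time_source <- function(grid, positions, S, f0, ramp_cycles = 3,
                                 smooth = TRUE, c_source = 1480,
                                 target = NULL) {
  omega <- 2 * pi * f0
  amps <- 1i * S / (omega * grid$spacing^3)
  positions <- matrix(positions, ncol = 3)
  if (!is.null(target)) {
    k <- omega / c_source
    ijk <- pos_to_voxel(grid, positions)
    vpos <- voxel_to_pos(grid, ijk)
    d <- sweep(positions, 2, target, "-")
    d <- -d / sqrt(rowSums(d^2))
    delta <- rowSums((vpos - positions) * d)
    amps <- amps * exp(1i * k * delta)
    positions <- vpos
  }
  raw_time_source(grid, positions, amps, f0, ramp_cycles,
                  smooth = smooth, c_source = c_source)
}

#' Direct piston-face time source for arrays inside the grid
#'
#' Discretizes every driven piston face at `>= samples_per_wavelength`
#' points per wavelength and injects the samples as baffled Rayleigh
#' monopoles (strength `2 i omega rho w ds` each, so the radiated field
#' reproduces the Rayleigh integral).  Used when the physical array fits
#' inside the simulation domain, e.g. for full-array reference runs and
#' scaled aberration studies.
#'
#' @param grid a [sim_grid()].
#' @param geometry an [generate_array()] object.
#' @param drives an [element_drive()].
#' @param medium coupling water properties.
#' @param target snap-phase re-projection focus (recommended).
#' @param samples_per_wavelength face sampling density.
#' @param ramp_cycles onset cycles.
#' @return a `time_source`.
#' @export
piston_time_source <- function(grid, geometry, drives,
                               medium = list(c = 1480, rho = 1000),
                               target = NULL,
                               samples_per_wavelength = 5,
                               ramp_cycles = 3) {
  lam <- medium$c / geometry$f0
  omega <- 2 * pi * geometry$f0
  pts <- NULL; S <- NULL
  active <- which(!drives$excluded & Mod(drives$weights) > 0)
  for (e in active) {
    sub <- piston_face_points(geometry$centers[e, ], geometry$normals[e, ],
                              geometry$element_radius, lam,
                              samples_per_wavelength)
    pts <- rbind(pts, sub$pts)
    S <- c(S, rep(2i * omega * medium$rho * drives$weights[e] * sub$ds,
                  nrow(sub$pts)))
  }
  monopole_time_source(grid, pts, S, geometry$f0, ramp_cycles,
                       c_source = medium$c, target = target)
}

#' Free-field array pressure by direct Rayleigh superposition
#'
#' Reference evaluation of the full-array field in homogeneous water,
#' without the solver: the superposed Rayleigh piston integrals of all
#' elements.  Used to verify the Huygens surface-source reduction.
#'
#' @param geometry an [generate_array()] object.
#' @param drives an [element_drive()].
#' @param points n x 3 field positions (m).
#' @param medium water properties.
#' @param subsamples_per_wavelength face sampling density.
#' @return complex pressures at `points`.
#' @export
array_free_field <- function(geometry, drives, points,
                             medium = list(c = 1480, rho = 1000),
                             subsamples_per_wavelength = 6) {
  points <- matrix(points, ncol = 3)
  p <- complex(real = numeric(nrow(points)), imaginary = numeric(nrow(points)))
  active <- which(!drives$excluded & Mod(drives$weights) > 0)
  for (e in active)
    p <- p + rayleigh_piston_field(geometry$centers[e, ],
                                   geometry$normals[e, ],
                                   geometry$element_radius,
                                   drives$weights[e], points, medium,
                                   geometry$f0, subsamples_per_wavelength)
  p
}
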