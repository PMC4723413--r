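#' CT volume container
#'
#' A voxel grid of Hounsfield units with spacing and origin metadata.
#'
#' @param voxels 3-D numeric array of Hounsfield units.
#' @param spacing per-axis voxel size (mm), strictly positive.
#' @param origin physical coordinate (mm) of voxel `(1,1,1)`.
#' @param axes axis-convention label (grid axes are aligned with the device
#'   frame; the geometric focus of the array is the coordinate origin).
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      axes = "device-aligned") {
  stopifnot(length(dim(voxels)) == 3, length(spacing) == 3,
            all(spacing > 0), length(origin) == 3)
  if (any(!is.finite(voxels))) stop("CT voxels must be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), axes = axes),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d @ %.3g mm, HU range [%g, %g]\n",
              d[1], d[2], d[3], x$spacing[1], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Synthetic skull phantom specification
#'
#' Parameters of the spherical-shell skull phantom standing in for a
#' registered nonhuman-primate CT: a ~7 cm cranium with configurable shell
#' thickness, an optional flat skull-base plate, and a smooth spatially
#' varying porosity texture.
#'
#' @param outer_radius_mm outer skull radius (mm).
#' @param thickness_mm shell thickness (mm); must equal
#'   `outer_radius_mm - inner_radius_mm`.
#' @param inner_radius_mm inner (brain) radius (mm).
#' @param center_mm centre of the cranium in device coordinates (mm).
#' @param base_plate_z_mm z-coordinate (mm) of the top surface of the flat
#'   skull-base plate, or `NULL` for no plate.
#' @param base_plate_thickness_mm plate thickness (mm).
#' @param base_plate_radius_mm lateral radius of the plate (mm).
#' @param porosity_mean mean porosity of the shell.
#' @param texture_amplitude standard deviation of the porosity texture.
#' @param texture_corr_mm 1/e autocorrelation length of the texture (mm).
#' @param seed RNG seed; the phantom is a pure function of (spec, seed).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_radius_mm = 35, thickness_mm = 2.5,
                         inner_radius_mm = outer_radius_mm - thickness_mm,
                         center_mm = c(0, 0, 0),
                         base_plate_z_mm = NULL,
                         base_plate_thickness_mm = 3,
                         base_plate_radius_mm = 1.2 * outer_radius_mm,
                         porosity_mean = 0.3, texture_amplitude = 0.15,
                         texture_corr_mm = 4, seed = 1) {
  if (thickness_mm < 0) stop("skull thickness must be >= 0")
  if (inner_radius_mm >= outer_radius_mm && thickness_mm > 0)
    stop("inconsistent radii: inner radius must be smaller than outer radius")
  if (abs(outer_radius_mm - thickness_mm - inner_radius_mm) > 1e-9)
    stop("inconsistent radii: thickness must equal outer - inner radius")
  if (porosity_mean < 0 || porosity_mean > 1)
    stop("mean porosity must lie in [0, 1]")
  structure(list(outer_radius_mm = outer_radius_mm,
                 thickness_mm = thickness_mm,
                 inner_radius_mm = inner_radius_mm,
                 center_mm = as.numeric(center_mm),
                 base_plate_z_mm = base_plate_z_mm,
                 base_plate_thickness_mm = base_plate_thickness_mm,
                 base_plate_radius_mm = base_plate_radius_mm,
                 porosity_mean = porosity_mean,
                 texture_amplitude = texture_amplitude,
                 texture_corr_mm = texture_corr_mm, seed = seed),
            class = "phantom_spec")
}

# smooth unit-variance Gaussian random field via spectral filtering;
# target autocorrelation exp(-r^2 / corr^2)
smooth_noise_field <- function(dims, spacing_mm, corr_mm, seed) {
  set.seed(seed)
  w <- array(rnorm(prod(dims)), dims)
  s <- corr_mm / 2 / spacing_mm   # kernel sd in voxels
  f <- function(n) {
    k <- 2 * pi * c(0:floor(n / 2), -rev(seq_len(ceiling(n / 2) - 1))) / n
    exp(-0.5 * (k * s)^2)
  }
  g <- outer(outer(f(dims[1]), f(dims[2])), f(dims[3]))
  dim(g) <- dims
  sm <- Re(fft(fft(w) * g, inverse = TRUE)) / prod(dims)
  sm / sd(sm)
}

#' Generate a synthetic pseudo-CT skull phantom
#'
#' Builds a spherical-shell skull (plus optional skull-base plate) with a
#' smooth porosity texture, expressed in Hounsfield units via
#' `H = 1000 (1 - psi)` so that the porosity mapping needs no clamping.
#' All non-skull voxels are at 0 HU (water/brain).
#'
#' @param spec a [phantom_spec()].
#' @param dims grid size (voxels).
#' @param spacing_mm isotropic voxel size (mm).
#' @param origin_mm coordinate of voxel `(1,1,1)` (mm); default centres the
#'   volume on the device origin.
#' @return a [ct_volume()] with HU in `[0, 1000]`.
#' @export
generate_skull_phantom <- function(spec, dims = c(96, 96, 96),
                                   spacing_mm = 1, origin_mm = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- as.integer(dims)
  if (is.null(origin_mm)) origin_mm <- -(dims - 1) / 2 * spacing_mm
  ax <- lapply(1:3, function(d) origin_mm[d] + (seq_len(dims[d]) - 1) * spacing_mm)
  hu <- array(0, dims)
  if (spec$thickness_mm == 0 && is.null(spec$base_plate_z_mm))
    return(ct_volume(hu, rep(spacing_mm, 3), origin_mm))

  dx2 <- outer(ax[[1]] - spec$center_mm[1], rep(1, dims[2]))^2
  r2 <- array(0, dims)
  for (k in seq_len(dims[3])) {
    r2[, , k] <- dx2 +
      outer(rep(1, dims[1]), (ax[[2]] - spec$center_mm[2])^2) +
      (ax[[3]][k] - spec$center_mm[3])^2
  }
  shell <- if (spec$thickness_mm > 0)
    r2 >= spec$inner_radius_mm^2 & r2 <= spec$outer_radius_mm^2
  else array(FALSE, dims)

  if (!is.null(spec$base_plate_z_mm)) {
    zmat <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
    lat2 <- array(0, dims)
    for (k in seq_len(dims[3]))
      lat2[, , k] <- dx2 + outer(rep(1, dims[1]),
                                 (ax[[2]] - spec$center_mm[2])^2)
    plate <- zmat <= spec$base_plate_z_mm &
      zmat >= spec$base_plate_z_mm - spec$base_plate_thickness_mm &
      lat2 <= spec$base_plate_radius_mm^2
    shell <- shell | plate
  }
  if (any(shell)) {
    psi <- array(spec$porosity_mean, dims)
    if (spec$texture_amplitude > 0)
      psi <- psi + spec$texture_amplitude *
        smooth_noise_field(dims, spacing_mm, spec$texture_corr_mm, spec$seed)
    psi <- pmin(pmax(psi, 0), 1)
    hu[shell] <- 1000 * (1 - psi[shell])
  }
  ct_volume(hu, rep(spacing_mm, 3), origin_mm)
}

#' Generate a hemispherical phased-array geometry
#'
#' Places `n_elements` circular-piston elements quasi-uniformly on a
#' hemisphere (deterministic Fibonacci-spiral lattice, bowl opening toward
#' +z), normals pointing at the geometric centre.
#'
#' @param n_elements number of elements.
#' @param hemisphere_diameter diameter (m).
#' @param element_radius piston radius (m); an error names the maximum
#'   feasible radius if elements would overlap.
#' @param f0 operating frequency (Hz).
#' @param seed integer; rotates the spiral azimuth (layout remains
#'   deterministic in (spec, seed)).
#' @return an object of class `array_geometry`.
#' @export
generate_array <- function(n_elements = 1024, hemisphere_diameter = 0.30,
                           element_radius = 0.005, f0 = 220e3, seed = 0) {
  stopifnot(n_elements >= 1, hemisphere_diameter > 0, element_radius > 0)
  R <- hemisphere_diameter / 2
  i <- seq_len(n_elements)
  # spiral lattice over cos(theta) in (-1, 0): lower hemisphere z < 0
  cz <- -(i - 0.5) / n_elements
  st <- sqrt(pmax(0, 1 - cz^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * i + 2 * pi * (seed %% 360) / 360
  centers <- unname(R * cbind(st * cos(phi), st * sin(phi), cz))
  normals <- -centers / R
  if (n_elements > 1) {
    dmin <- min(dist(centers))
    if (dmin < 2 * element_radius)
      stop(sprintf(paste0("elements overlap: minimum centre distance %.4g m ",
                          "allows a maximum element radius of %.4g m"),
                   dmin, dmin / 2))
  }
  structure(list(centers = centers, normals = normals,
                 element_radius = element_radius, f0 = f0,
                 hemisphere_radius = R, focus = c(0, 0, 0)),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry> %d elements, R = %.3g m, a = %.3g m, f0 = %.3g kHz\n",
              nrow(x$centers), x$hemisphere_radius, x$element_radius,
              x$f0 / 1e3))
  invisible(x)
}

#' Generate a passive cavitation detector geometry
#'
#' A weakly focused rectangular aperture (40 x 7 mm, 15 cm radius of
#' curvature) centred a given distance laterally from the geometric focus,
#' aimed at the focus.
#'
#' @param offset_from_focus lateral offset (m), > 0.
#' @param side `"left"` (negative x) or `"right"`.
#' @param f0 operating frequency (Hz).
#' @param aperture_length,aperture_width aperture dimensions (m).
#' @param radius_of_curvature focusing curvature (m).
#' @return an object of class `pcd_geometry`.
#' @export
generate_pcd <- function(offset_from_focus = 0.10, side = c("left", "right"),
                         f0 = 610e3, aperture_length = 0.040,
                         aperture_width = 0.007,
                         radius_of_curvature = 0.15) {
  side <- match.arg(side)
  stopifnot(offset_from_focus > 0, aperture_length > 0, aperture_width > 0)
  sgn <- if (side == "left") -1 else 1
  center <- c(sgn * offset_from_focus, 0, 0)
  orient <- -center / sqrt(sum(center^2))
  structure(list(center = center, aperture_length = aperture_length,
                 aperture_width = aperture_width,
                 radius_of_curvature = radius_of_curvature,
                 f0 = f0, orientation = orient, side = side),
            class = "pcd_geometry")
}

#' Write / read a CT volume as NIfTI-1
#'
#' HU values are stored as 16-bit integers with spacing in the header, so
#' the volume round-trips bit-exactly.
#'
#' @param ct a [ct_volume()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `write_ct_nifti` returns `path` invisibly; `read_ct_nifti`
#'   returns a [ct_volume()].
#' @export
write_ct_nifti <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  d <- dim(ct$voxels)
  hdr <- RNifti::niftiHeader(list(dim = c(3L, d, 1L, 1L, 1L, 1L),
                                  pixdim = c(1, ct$spacing, 1, 1, 1, 1),
                                  datatype = 4L))
  img <- RNifti::asNifti(array(as.integer(round(ct$voxels)), d),
                         reference = hdr, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ct_nifti
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim(img)),
            spacing = RNifti::pixdim(img)[1:3])
}

#' Write / read device geometry as YAML
#'
#' @param geom an [generate_array()] or [generate_pcd()] object.
#' @param path YAML file path.
#' @export
write_geometry_yaml <- function(geom, path) {
  obj <- lapply(unclass(geom), function(v) {
    if (is.matrix(v)) apply(v, 1, as.numeric, simplify = FALSE) else v
  })
  obj$.class <- class(geom)[1]
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_geometry_yaml
#' @export
read_geometry_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  for (nm in c("centers", "normals"))
    if (!is.null(obj[[nm]]) && is.list(obj[[nm]]))
      obj[[nm]] <- unname(do.call(rbind, obj[[nm]]))
  for (nm in c("center", "orientation", "focus"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.numeric(obj[[nm]])
  structure(obj, class = cls)
}
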