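#' Interpolation of the focal region
#'
#' Extracts a cubic window around `center` from the max-pressure field and
#' upsamples it.  The default Catmull-Rom cubic interpolant passes through
#' the samples without ringing; it is the right choice for max-pressure
#' envelopes, which are not band-limited (|amplitude| has kinks at nulls,
#' and spectral upsampling then overshoots at the focal peak by several
#' percent, which distorts normalized iso-dB volumes).  `"spectral"`
#' (zero-padded FFT) is exact for periodic band-limited data and is used
#' by the interpolation oracle tests.  Both preserve the original samples,
#' so the peak never decreases.
#'
#' @param result a `sim_result` or a 3-D array.
#' @param grid the [sim_grid()] (taken from `result` when omitted).
#' @param center window centre (m); defaults to the field peak.
#' @param half_extent half window size (m).
#' @param resolution target fine spacing (m); realized as the nearest
#'   integer upsampling factor (at most 10).
#' @param method `"cubic"` (default) or `"spectral"`.
#' @return an object of class `focal_field`: fine `field`, `spacing` (m),
#'   `origin` (m), `dims`.
#' @export
interpolate_focus <- function(result, grid = NULL, center = NULL,
                              half_extent = 15e-3, resolution = 0.1e-3,
                              method = c("cubic", "spectral")) {
  method <- match.arg(method)
  if (inherits(result, "sim_result")) {
    if (is.null(grid)) grid <- result$grid
    field <- result$pmax
  } else field <- result
  stopifnot(!is.null(grid))
  dx <- grid$spacing
  # integer upsampling factor nearest the requested resolution (capped:
  # beyond 10x the band-limited field adds no information)
  m <- max(1L, min(10L, as.integer(round(dx / resolution))))
  if (is.null(center)) {
    am <- arrayInd(which.max(field), dim(field))
    center <- voxel_to_pos(grid, am)[1, ]
  }
  hw <- round(half_extent / dx)
  cv <- pos_to_voxel(grid, center)[1, ]
  lo <- cv - hw; hi <- cv + hw
  if (any(lo < 1) || any(hi > grid$dims)) {
    ov <- pmin(hi, grid$dims) - pmax(lo, 1) + 1
    stop(sprintf(paste0("interpolation window clipped by the grid boundary ",
                        "(overlap %d x %d x %d of %d voxels per axis)"),
                 ov[1], ov[2], ov[3], 2 * hw + 1))
  }
  win <- field[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  nd <- dim(win)
  fine <- if (method == "spectral")
    spectral_upsample_cpp(as.numeric(win), nd, as.integer(m))
  else
    cubic_upsample_cpp(as.numeric(win), nd, as.integer(m))
  fine <- array(fine, nd * m)
  structure(list(field = fine, spacing = dx / m,
                 origin = voxel_to_pos(grid, lo)[1, ],
                 dims = dim(fine), coarse_dims = nd, factor = m),
            class = "focal_field")
}

#' Iso-dB volume of a pressure field
#'
#' Volume of the region where the field exceeds `threshold_db` relative to
#' the reference peak.
#'
#' @param field a `focal_field`, `sim_result` or array.
#' @param threshold_db threshold in dB (negative).
#' @param reference_peak reference pressure (Pa); default is the field max.
#' @param voxel_volume_mm3 voxel volume in mm^3 (derived automatically for
#'   `focal_field` / `sim_result` inputs).
#' @return volume in mm^3.
#' @export
iso_volume <- function(field, threshold_db, reference_peak = NULL,
                       voxel_volume_mm3 = NULL) {
  if (threshold_db >= 0) stop("threshold must be negative (dB re peak)")
  if (inherits(field, "focal_field")) {
    if (is.null(voxel_volume_mm3)) voxel_volume_mm3 <- (field$spacing * 1e3)^3
    field <- field$field
  } else if (inherits(field, "sim_result")) {
    if (is.null(voxel_volume_mm3))
      voxel_volume_mm3 <- (field$grid$spacing * 1e3)^3
    field <- field$pmax
  }
  stopifnot(!is.null(voxel_volume_mm3))
  if (is.null(reference_peak)) reference_peak <- max(field)
  if (reference_peak <= 0) stop("reference peak must be positive")
  thr <- reference_peak * 10^(threshold_db / 20)
  sum(field >= thr) * voxel_volume_mm3
}

#' Convert a dB level relative to a peak pressure to absolute pressure
#'
#' @param peak peak pressure (any unit, e.g. kPa).
#' @param level_db level in dB relative to the peak.
#' @return pressure in the same unit as `peak`.
#' @export
db_to_pressure <- function(peak, level_db) {
  stopifnot(all(peak > 0))
  peak * 10^(level_db / 20)
}

#' @rdname db_to_pressure
#' @param pressure pressure in the same unit as `peak`.
#' @export
pressure_to_db <- function(pressure, peak) 20 * log10(pressure / peak)

#' Sub-voxel focal peak location and value
#'
#' Interpolation of a small window around the coarse argmax,
#' followed by a separable quadratic refinement of the fine-grid maximum.
#' Ties among equal coarse maxima are broken toward the smaller axial (z)
#' coordinate and flagged.
#'
#' @param result `sim_result` or array.
#' @param grid the [sim_grid()].
#' @param half_extent,resolution interpolation window parameters (m).
#' @param exclude_source mask out the injected source voxels (and the PML)
#'   before the peak search; their singular near field otherwise dominates.
#' @param search_center optional focal-region centre (m): the argmax is
#'   then restricted to within `search_radius` of it, the way beam peaks
#'   are evaluated at the intended focus.
#' @param search_radius search-ball radius (m).
#' @return list with `value` (Pa), `position` (m), `tie` flag.
#' @export
focal_peak <- function(result, grid = NULL, half_extent = 5e-3,
                       resolution = 0.1e-3, exclude_source = TRUE,
                       search_center = NULL, search_radius = 8e-3) {
  if (inherits(result, "sim_result")) {
    if (is.null(grid)) grid <- result$grid
    field <- result$pmax
    # the injected surface/aperture voxels carry a singular near field;
    # exclude them (and the PML) from the peak search
    if (exclude_source && !is.null(result$source_mask_idx0))
      field[result$source_mask_idx0 + 1] <- 0
    field[!interior_mask(grid)] <- 0
  } else field <- result
  if (!is.null(search_center)) {
    # restrict the argmax to the intended focal region: reverberant hot
    # spots between strong reflectors (e.g. the skull base) can exceed
    # the focal pressure far from the target
    ax <- lapply(1:3, function(d) grid_axis(grid, d))
    r2 <- outer(outer((ax[[1]] - search_center[1])^2,
                      (ax[[2]] - search_center[2])^2, "+"),
                (ax[[3]] - search_center[3])^2, "+")
    field[r2 > search_radius^2] <- 0
  }
  mx <- max(field)
  cand <- which(field == mx)
  tie <- length(cand) > 1
  if (tie) {
    ind <- arrayInd(cand, dim(field))
    cand <- cand[order(ind[, 3], ind[, 1], ind[, 2])][1]
  }
  cv <- arrayInd(cand[1], dim(field))[1, ]
  # keep the window inside the grid
  hw <- round(half_extent / grid$spacing)
  cv <- pmin(pmax(cv, hw + 1), grid$dims - hw)
  ff <- interpolate_focus(field, grid, center = voxel_to_pos(grid, cv)[1, ],
                          half_extent = half_extent, resolution = resolution)
  fi <- arrayInd(which.max(ff$field), ff$dims)[1, ]
  pos <- ff$origin + (fi - 1) * ff$spacing
  # separable quadratic refinement
  val <- max(ff$field)
  for (d in 1:3) {
    i <- fi[d]
    if (i <= 1 || i >= ff$dims[d]) next
    idx <- fi; idx[d] <- i - 1; ym <- ff$field[matrix(idx, 1)]
    idx[d] <- i + 1; yp <- ff$field[matrix(idx, 1)]
    den <- ym - 2 * val + yp
    if (den < 0) pos[d] <- pos[d] + 0.5 * (ym - yp) / den * ff$spacing
  }
  list(value = val, position = pos, tie = tie)
}

#' Signed focal peak shift between two fields
#'
#' Difference of the interpolated peak positions projected on the beam
#' axis.  With the axis pointing from the transducer toward the far field,
#' negative shifts are prefocal (toward the transducer).
#'
#' @param field_a,field_b `sim_result` objects on the same grid.
#' @param axis beam-axis unit vector.
#' @param search_center optional intended-focus position (m) for both
#'   peak searches.
#' @return shift in mm (attribute `tie` flags degenerate maxima).
#' @export
peak_shift <- function(field_a, field_b, axis = c(0, 0, 1),
                       search_center = NULL) {
  ga <- field_a$grid; gb <- field_b$grid
  if (!all(ga$dims == gb$dims) || ga$spacing != gb$spacing)
    stop("fields must share a grid")
  axis <- axis / sqrt(sum(axis^2))
  pa <- focal_peak(field_a, search_center = search_center)
  pb <- focal_peak(field_b, search_center = search_center)
  out <- sum((pa$position - pb$position) * axis) * 1e3
  attr(out, "tie") <- pa$tie || pb$tie
  out
}

#' Beam metrics of a simulation result
#'
#' Peak pressure and position, optional peak shift against a reference run,
#' and iso-dB volumes: main-beam thresholds (-3.5, -7 dB) on the 0.1 mm
#' interpolated focal window, side-lobe thresholds (-12, -14 dB) on the
#' coarse grid over the interior (PML excluded).
#'
#' @param result a `sim_result`.
#' @param reference optional reference `sim_result` (for the shift).
#' @param axis beam axis for the shift.
#' @param thresholds_fine,thresholds_coarse dB thresholds.
#' @param half_extent focal window half size (m).
#' @param center optional intended-focus position (m); the peak search is
#'   then confined to its neighbourhood.
#' @return a one-row `data.frame`.
#' @export
beam_metrics <- function(result, reference = NULL, axis = c(0, 0, 1),
                         thresholds_fine = c(-3.5, -7),
                         thresholds_coarse = c(-12, -14),
                         half_extent = 15e-3, center = NULL) {
  grid <- result$grid
  pk <- focal_peak(result, search_center = center)
  ff <- interpolate_focus(result, center = pk$position,
                          half_extent = half_extent)
  peak <- max(pk$value, max(ff$field))
  out <- data.frame(peak_Pa = peak,
                    x_mm = pk$position[1] * 1e3,
                    y_mm = pk$position[2] * 1e3,
                    z_mm = pk$position[3] * 1e3)
  out$shift_mm <- if (!is.null(reference))
    as.numeric(peak_shift(result, reference, axis,
                          search_center = center)) else NA_real_
  for (th in thresholds_fine)
    out[[sprintf("vol_%gdB_mm3", -th)]] <-
      iso_volume(ff, th, reference_peak = peak)
  coarse <- result$pmax
  if (!is.null(result$source_mask_idx0))
    coarse[result$source_mask_idx0 + 1] <- 0
  interior <- interior_mask(grid)
  vox3 <- (grid$spacing * 1e3)^3
  for (th in thresholds_coarse)
    out[[sprintf("vol_%gdB_mm3", -th)]] <-
      sum(coarse[interior] >= peak * 10^(th / 20)) * vox3
  out
}
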