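#' Simulate the PCD spatial sensitivity map by reciprocity
#'
#' Models the passive cavitation detector as a transmitter: its weakly
#' focused rectangular aperture is discretized on its spherical cap at
#' >= 4 samples per wavelength, injected as baffled Rayleigh monopoles and
#' propagated through the material maps with the acoustic solver.  The
#' normalized maximum-pressure field is the receive-sensitivity map.
#'
#' @param pcd a [generate_pcd()] object.
#' @param maps a `material_maps` object.
#' @param grid a [sim_grid()]; spacing must be <= lambda_water/6 at
#'   `frequency`.
#' @param frequency transmit frequency (Hz); defaults to the PCD resonance.
#' @param samples_per_wavelength aperture sampling density.
#' @return an object of class `sensitivity_map`: normalized `map` in
#'   `[0, 1]` (max exactly 1), `frequency`, `pcd`, and the underlying
#'   `sim_result`.
#' @export
pcd_transmit_field <- function(pcd, maps, grid, frequency = pcd$f0,
                               samples_per_wavelength = 4) {
  stopifnot(inherits(pcd, "pcd_geometry"))
  c_w <- maps$constants$c_water
  lam <- c_w / frequency
  if (grid$spacing > lam / 6)
    stop(sprintf("grid too coarse for %g kHz: need spacing <= %.3g mm",
                 frequency / 1e3, lam / 6 * 1e3))
  ap <- pcd_aperture_points(pcd, lam / samples_per_wavelength)
  omega <- 2 * pi * frequency
  rho_w <- maps$constants$rho_water
  # baffled Rayleigh monopole strengths for unit normal velocity
  S <- rep(2i * omega * rho_w * ap$ds, nrow(ap$pts))
  roc_focus <- pcd$center + pcd$radius_of_curvature * pcd$orientation
  src <- monopole_time_source(grid, ap$pts, S, frequency, target = roc_focus)
  res <- run_acoustic(maps, src, grid, record_start = "crossing")
  m <- res$pmax / max(res$pmax)
  structure(list(map = m, frequency = frequency, pcd = pcd, result = res),
            class = "sensitivity_map")
}

# sample the spherically curved rectangular aperture; returns points and
# per-point area
pcd_aperture_points <- function(pcd, h) {
  nu <- max(4, ceiling(pcd$aperture_length / h))
  nv <- max(2, ceiling(pcd$aperture_width / h))
  u <- (seq_len(nu) - (nu + 1) / 2) * pcd$aperture_length / nu
  v <- (seq_len(nv) - (nv + 1) / 2) * pcd$aperture_width / nv
  g <- expand.grid(u = u, v = v)
  b <- orthonormal_basis(pcd$orientation)
  roc <- pcd$radius_of_curvature
  sag <- roc - sqrt(pmax(0, roc^2 - g$u^2 - g$v^2))
  pts <- cbind(pcd$center[1] + g$u * b$e1[1] + g$v * b$e2[1] + sag * pcd$orientation[1],
               pcd$center[2] + g$u * b$e1[2] + g$v * b$e2[2] + sag * pcd$orientation[2],
               pcd$center[3] + g$u * b$e1[3] + g$v * b$e2[3] + sag * pcd$orientation[3])
  list(pts = pts,
       ds = pcd$aperture_length * pcd$aperture_width / nrow(pts))
}

#' Combined FUS x PCD sensitivity map
#'
#' Voxel-wise product of the two normalized fields, renormalized to max 1.
#'
#' @param fus_field `sim_result`, `sensitivity_map` or array.
#' @param pcd_map `sensitivity_map` or array on the same grid.
#' @return array with maximum exactly 1 (all zero if supports are disjoint).
#' @export
combined_map <- function(fus_field, pcd_map) {
  a <- as_field_array(fus_field)
  b <- as_field_array(pcd_map)
  if (!all(dim(a) == dim(b))) stop("fields are on different grids")
  prod <- (a / max(a)) * (b / max(b))
  m <- max(prod)
  if (m > 0) prod / m else prod
}

as_field_array <- function(x) {
  if (inherits(x, "sim_result")) x$pmax
  else if (inherits(x, "sensitivity_map")) x$map
  else x
}

#' Fraction of the FUS focal volume visible to the PCD
#'
#' Fraction of the -6 dB FUS voxels that also lie inside the -6 dB region
#' of the combined FUS x PCD map.
#'
#' @param combined combined map (array or `sensitivity_map`).
#' @param fus_field FUS field (array or `sim_result`).
#' @param threshold_db threshold (dB, negative).
#' @return fraction in `[0, 1]`.
#' @export
intersection_fraction <- function(combined, fus_field, threshold_db = -6) {
  a <- as_field_array(combined)
  b <- as_field_array(fus_field)
  if (!all(dim(a) == dim(b))) stop("fields are on different grids")
  thr <- 10^(threshold_db / 20)
  if (max(b) <= 0) stop("empty FUS threshold set")
  fus_set <- b >= max(b) * thr
  comb_set <- a >= max(a) * thr
  sum(comb_set & fus_set) / sum(fus_set)
}
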