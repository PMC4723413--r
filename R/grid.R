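#' Simulation grid
#'
#' Defines the cubic-cell finite grid used by both pseudospectral solvers.
#' Cell spacing is isotropic; the time step is derived from the
#' Courant-Friedrichs-Lewy (CFL) number and the fastest sound speed in the
#' material maps at run time.
#'
#' @param dims integer vector of length 3, grid points per axis.  Dimensions
#'   that factor into 2, 3 and 5 give the fastest transforms; see
#'   [good_grid_size()].
#' @param spacing cell size in metres (scalar, isotropic).
#' @param origin physical coordinate (m) of the centre of voxel `(1,1,1)`.
#'   Default places the grid centre at the coordinate origin.
#' @param duration total simulated time in seconds.
#' @param cfl CFL number `c_max * dt / dx`; must be <= 0.3 (the stability
#'   margin used for heterogeneous maps).
#' @param pml_size thickness of the perfectly matched layer in voxels.
#' @param pml_alpha peak PML absorption in nepers per grid point (quartic
#'   profile).
#' @return an object of class `sim_grid`.
#' @export
sim_grid <- function(dims, spacing, origin = NULL, duration,
                     cfl = 0.3, pml_size = 10, pml_alpha = 2) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), length(spacing) == 1,
            spacing > 0, duration > 0)
  if (cfl <= 0 || cfl > 0.3)
    stop("CFL number must lie in (0, 0.3]")
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  stopifnot(length(origin) == 3)
  structure(list(dims = dims, spacing = spacing, origin = as.numeric(origin),
                 duration = duration, cfl = cfl,
                 pml_size = as.integer(pml_size), pml_alpha = pml_alpha),
            class = "sim_grid")
}

#' Round a grid dimension up to a 5-smooth size
#'
#' The internal FFT is fastest when every dimension factors into 2, 3 and 5.
#'
#' @param n requested minimum size.
#' @return the smallest integer `>= n` whose prime factors are all <= 5.
#' @export
good_grid_size <- function(n) {
  vapply(as.integer(n), next_smooth_cpp, integer(1))
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d x %d, dx = %.3g mm, T = %.3g us, CFL %.2f, PML %d\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing * 1e3,
              x$duration * 1e6, x$cfl, x$pml_size))
  invisible(x)
}

# coordinate vector along one axis (m)
grid_axis <- function(grid, d) {
  grid$origin[d] + (seq_len(grid$dims[d]) - 1) * grid$spacing
}

# nearest voxel (i, j, k) for physical positions; pos is n x 3 (m)
pos_to_voxel <- function(grid, pos) {
  pos <- matrix(pos, ncol = 3)
  ijk <- sweep(pos, 2, grid$origin, "-") / grid$spacing
  ijk <- round(ijk) + 1
  bad <- ijk < 1 | sweep(ijk, 2, grid$dims, ">")
  if (any(bad))
    stop("position(s) outside the simulation grid")
  storage.mode(ijk) <- "integer"
  ijk
}

# 0-based linear voxel index for the C++ cores
voxel_lin0 <- function(grid, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  (ijk[, 1] - 1L) + grid$dims[1] * ((ijk[, 2] - 1L) +
    grid$dims[2] * (ijk[, 3] - 1L))
}

# physical position (m) of voxel centres
voxel_to_pos <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep((ijk - 1) * grid$spacing, 2, grid$origin, "+")
}

# time step from CFL and the fastest medium speed
grid_dt <- function(grid, c_max) grid$cfl * grid$spacing / c_max

# logical mask of the interior region (PML excluded), as an array
interior_mask <- function(grid) {
  m <- array(TRUE, grid$dims)
  p <- grid$pml_size
  if (p > 0) {
    for (d in 1:3) {
      if (grid$dims[d] <= 2 * p + 1) next
      idx <- c(seq_len(p), grid$dims[d] - seq_len(p) + 1)
      if (d == 1) m[idx, , ] <- FALSE
      if (d == 2) m[, idx, ] <- FALSE
      if (d == 3) m[, , idx] <- FALSE
    }
  }
  m
}
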