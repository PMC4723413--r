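test_that("measured corrections in water reduce to geometry", {
  # small array fully inside the grid, homogeneous water, point source at
  # the geometric centre: measured phases must equal the water time of
  # flight and measured amplitudes must be equal across the sphere
  fx <- fixture("water_corrections", function() {
    f0 <- 220e3
    geom <- generate_array(64, 0.09, 0.003, f0 = f0)
    grid <- sim_grid(c(80, 80, 80), 1.4e-3, duration = 70e-6)
    maps <- uniform_maps(grid, "water")
    corr <- measure_corrections(maps, geom, c(0, 0, 0), grid)
    list(geom = geom, grid = grid, corr = corr, f0 = f0)
  })
  corr <- fx$corr
  # amplitude falls off as 1/distance from the (snapped) source, so the
  # spherical-spreading-compensated amplitudes are equal
  # phases match the water time of flight: element centres are snapped to
  # voxels, so compare against the snapped distances
  vp <- skullwave:::voxel_to_pos(fx$grid,
                                 skullwave:::pos_to_voxel(fx$grid,
                                                          fx$geom$centers))
  sp <- skullwave:::voxel_to_pos(fx$grid,
                                 skullwave:::pos_to_voxel(fx$grid,
                                                          c(0, 0, 0)))[1, ]
  k <- 2 * pi * fx$f0 / 1480
  d <- sqrt(rowSums(sweep(vp, 2, sp, "-")^2))
  expected <- k * d
  resid <- Arg(exp(1i * (corr$phase - expected)))
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 2 * pi / 180)
  amp_comp <- corr$amplitude * d
  expect_lt(sd(amp_comp) / mean(amp_comp), 0.02)

  # phase-only correction of these measurements reproduces the steering
  # drive for the same (snapped) geometry
  snapped <- fx$geom
  snapped$centers <- vp
  steer <- steering_phases(snapped, sp)
  drv <- apply_correction(element_drive(rep(1 + 0i, 64)), corr, "phase")
  dphi <- Arg(drv$weights / steer$weights)
  dphi <- Arg(exp(1i * (dphi - mean(dphi))))
  expect_lt(sqrt(mean(dphi^2)), 2 * pi / 180)
})

test_that("correction schemes conserve power and apply the clipping rule", {
  set.seed(1)
  n <- 128
  corr <- structure(list(phase = runif(n, -pi, pi),
                         amplitude = runif(n, 0.5, 2)),
                    class = "correction_set")
  drives <- steering_phases(test_array(), c(0.01, 0, 0))
  p0 <- sum(Mod(drives$weights)^2)
  for (sch in c("phase", "phase_amplitude", "phase_inverse_amplitude")) {
    out <- apply_correction(drives, corr, sch)
    expect_equal(sum(Mod(out$weights)^2), p0, tolerance = 1e-9)
  }
  # identity scheme
  expect_identical(apply_correction(drives, corr, "none"), drives)
  # uniform amplitudes exclude nothing
  cu <- structure(list(phase = corr$phase, amplitude = rep(1, n)),
                  class = "correction_set")
  expect_false(any(apply_correction(drives, cu, "phase_amplitude")$excluded))
  # a strongly shadowed element (tiny amplitude -> huge required drive)
  cs <- cu; cs$amplitude[5] <- 1e-4
  out <- apply_correction(drives, cs, "phase_amplitude")
  expect_true(out$excluded[5])
  expect_equal(Mod(out$weights[5]), 0)
  # degenerate: everything excluded on input
  expect_error(apply_correction(element_drive(rep(0 + 0i, n),
                                              rep(TRUE, n)),
                                cu, "phase_amplitude"), "excluded")
})

test_that("elements behind a thickened skull patch receive less signal", {
  fx <- aberration_fixture()
  # add a thick, strongly absorbing (high-porosity) shell segment on -x:
  # the square-root porosity law makes porous bone the lossy case
  spec2 <- phantom_spec(outer_radius_mm = 26, thickness_mm = 12,
                        porosity_mean = 0.7, texture_amplitude = 0,
                        seed = 7)
  ct2 <- generate_skull_phantom(spec2, dims = fx$grid$dims,
                                spacing_mm = 1.4)
  # keep the thickened shell only on the -x side
  axv <- skullwave:::grid_axis(fx$grid, 1) * 1e3
  patch <- ct2
  patch$voxels[axv > -10, , ] <- 0
  base_ct <- generate_skull_phantom(
    phantom_spec(outer_radius_mm = 26, thickness_mm = 3.5,
                 porosity_mean = 0.35, texture_amplitude = 0.25,
                 texture_corr_mm = 5, seed = 7),
    dims = fx$grid$dims, spacing_mm = 1.4)
  merged <- base_ct
  merged$voxels <- pmax(base_ct$voxels, patch$voxels)
  maps2 <- build_material_maps(merged, 300)
  corr2 <- measure_corrections(maps2, fx$geom, fx$target, fx$grid)
  # "behind" = target-to-element rays pointing into the patch cone, so the
  # ray actually crosses the thickened segment
  dir <- sweep(fx$geom$centers, 2, fx$target, "-")
  dir <- dir / sqrt(rowSums(dir^2))
  behind <- dir[, 1] < -0.85
  ratio <- corr2$amplitude / fx$corr$amplitude
  # attenuation behind the patch exceeds that of unshadowed elements
  expect_lt(median(ratio[behind]), 0.9 * median(ratio[!behind]))
})
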