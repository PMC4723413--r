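# 1-D elastic interface fixture: water | skull-bone half-space along x
elastic_interface_run <- function(lossy = FALSE) {
  nx <- 300
  grid <- sim_grid(c(nx, 1, 1), 1e-3, duration = 175e-6)
  i_src <- 30L; i_int <- 180L; i_sen <- 236L
  dims <- c(nx, 1, 1)
  cp <- array(1480, dims); cs <- array(0, dims)
  rho <- array(1000, dims); ap <- array(0, dims); as_ <- array(0, dims)
  cp[i_int:nx] <- 3100; cs[i_int:nx] <- 3100 * 4 / 7
  rho[i_int:nx] <- 2200
  if (lossy) { ap[i_int:nx] <- 10; as_[i_int:nx] <- 10 * 90 / 85 }
  maps <- structure(list(c_p = cp, c_s = cs, alpha_p = ap, alpha_s = as_,
                         rho = rho, spacing_mm = rep(1, 3)),
                    class = "material_maps")
  co <- to_viscoelastic(maps, 220e3)
  src <- skullwave:::raw_time_source(
    grid, skullwave:::voxel_to_pos(grid, c(i_src, 1, 1)), 1 + 0i, 220e3)
  sensor <- skullwave:::voxel_to_pos(grid, c(i_sen, 1, 1))
  run_elastic(co, src, grid, sensors = sensor, record_start = "none",
              shear_diagnostics = TRUE)
}

test_that("the fluid limit of the elastic solver reproduces the acoustic field", {
  fl <- fluid_limit_pair()
  pa <- focal_peak(fl$acoustic); pe <- focal_peak(fl$elastic)
  expect_equal(pe$value / pa$value, 1, tolerance = 0.01)
  expect_equal(pe$position, pa$position, tolerance = 1e-3)
})

test_that("normal incidence on a solid transmits like a fluid and makes no shear", {
  run <- fixture("elastic_interface_lossless",
                 function() elastic_interface_run(FALSE))
  # reference amplitude: same source and sensor through homogeneous water,
  # also in the elastic solver (the absolute source scale cancels); water
  # is slower, so the run is longer for the same steady-fit window
  nx <- 300
  grid <- sim_grid(c(nx, 1, 1), 1e-3, duration = 215e-6)
  dims <- c(nx, 1, 1)
  mapsw <- structure(list(c_p = array(1480, dims), c_s = array(0, dims),
                          alpha_p = array(0, dims), alpha_s = array(0, dims),
                          rho = array(1000, dims), spacing_mm = rep(1, 3)),
                     class = "material_maps")
  src <- skullwave:::raw_time_source(
    grid, skullwave:::voxel_to_pos(grid, c(30, 1, 1)), 1 + 0i, 220e3)
  sensor <- skullwave:::voxel_to_pos(grid, c(236, 1, 1))
  ref <- run_elastic(to_viscoelastic(mapsw, 220e3), src, grid,
                     sensors = sensor, record_start = "none")
  a1 <- skullwave:::steady_amplitude(run$traces[, 1], run$dt, 220e3, 8)
  a0 <- skullwave:::steady_amplitude(ref$traces[, 1], ref$dt, 220e3, 8)
  T_an <- analytic_transmission(list(c1 = 1480, rho1 = 1000,
                                     c2 = 3100, rho2 = 2200))$transmission
  # the solver records mean normal stress; for a longitudinal wave in a
  # solid the lateral stresses are lambda/(lambda+2mu) of the axial one,
  # so the recorded "pressure" is (1 + 2 lambda/(lambda+2mu))/3 of the
  # transmitted axial stress that the interface coefficient refers to
  lam_ratio <- 1 - 2 * (4 / 7)^2
  expect_equal(a1 / a0, T_an * (1 + 2 * lam_ratio) / 3, tolerance = 0.02)
  # no mode conversion at normal incidence
  expect_lt(run$shear_energy / run$solid_kinetic_energy, 1e-4)
})

test_that("Kelvin-Voigt losses attenuate at the rate set by the absorption maps", {
  lossless <- fixture("elastic_interface_lossless",
                      function() elastic_interface_run(FALSE))
  lossy <- elastic_interface_run(TRUE)
  aL <- skullwave:::steady_amplitude(lossless$traces[, 1], lossless$dt,
                                     220e3, 8)
  aA <- skullwave:::steady_amplitude(lossy$traces[, 1], lossy$dt, 220e3, 8)
  # 10 dB/(MHz cm) over 56 mm of bone at 220 kHz
  expected <- 10^(-(10 * 0.22 * 5.6) / 20)
  expect_equal(aA / aL, expected, tolerance = 0.1)
  expect_lt(aA, aL)
})

test_that("oblique incidence beyond the critical angle converts to shear", {
  # a tapered-aperture burst launched obliquely at a dense-bone half space;
  # the rotational/dilatational energy split in the solid is measured while
  # the directly transmitted pulse is inside it (continuous-wave driving
  # would accumulate reverberant multi-bounce conversion instead)
  frac <- function(angle_deg) {
    n1 <- 144; n3 <- 96
    grid <- sim_grid(c(n1, 1, n3), 1e-3, duration = 34e-6)
    dims <- c(n1, 1, n3)
    cp <- array(1480, dims); cs <- array(0, dims); rho <- array(1000, dims)
    sol <- 61:n3
    cp[, , sol] <- 3100; cs[, , sol] <- 3100 * 4 / 7; rho[, , sol] <- 2200
    maps <- structure(list(c_p = cp, c_s = cs,
                           alpha_p = array(0, dims), alpha_s = array(0, dims),
                           rho = rho, spacing_mm = rep(1, 3)),
                      class = "material_maps")
    co <- to_viscoelastic(maps, 220e3)
    k <- 2 * pi * 220e3 / 1480
    ix <- 15:(n1 - 14)
    x <- (ix - (n1 + 1) / 2) * grid$spacing
    pos <- cbind(x, 0, x * 0 + (36 - (n3 + 1) / 2) * grid$spacing)
    w <- 0.5 - 0.5 * cos(2 * pi * seq_along(ix) / (length(ix) + 1))
    amps <- w * exp(1i * k * sin(angle_deg * pi / 180) * x)
    src <- skullwave:::raw_time_source(grid, pos, amps, 220e3)
    src$stop_time <- 9 / 220e3
    run <- run_elastic(co, src, grid, record_start = "none",
                       shear_diagnostics = TRUE)
    run$shear_energy / run$solid_kinetic_energy
  }
  f0 <- frac(0); f20 <- frac(20); f40 <- frac(40)
  # negligible conversion at normal incidence, growing with angle, and
  # shear-dominated past the longitudinal critical angle (28.5 degrees)
  expect_lt(f0, 0.1 * f20)
  expect_lt(f20, f40)
  expect_gt(f40, 0.5)
})


test_that("shear conversion and absorption lower the focal peak through a thin shell", {
  # thin textured shell between a converging cap and its focus: the
  # viscoelastic run loses energy to shear modes that the fluid model
  # does not, so its focal peak must not exceed the acoustic one
  grid <- sim_grid(c(60, 60, 60), 1.6e-3, duration = 55e-6)
  spec <- phantom_spec(outer_radius_mm = 20, thickness_mm = 3,
                       porosity_mean = 0.3, texture_amplitude = 0.15,
                       texture_corr_mm = 3, seed = 3)
  ct <- generate_skull_phantom(spec, dims = grid$dims, spacing_mm = 1.6)
  maps <- build_material_maps(ct, 300)
  src <- cap_source(grid, radius = 0.030, n = 220)
  ra <- run_acoustic(maps, src, grid, record_start = "crossing")
  re <- run_elastic(to_viscoelastic(maps, 220e3), src, grid,
                    record_start = "crossing")
  pa <- focal_peak(ra, search_center = c(0, 0, 0), search_radius = 6e-3)
  pe <- focal_peak(re, search_center = c(0, 0, 0), search_radius = 6e-3)
  expect_lte(pe$value, pa$value * 1.02)
})
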