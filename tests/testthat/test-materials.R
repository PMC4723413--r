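test_that("Hounsfield-to-porosity mapping is linear and clamped", {
  expect_equal(hounsfield_to_porosity(1000), 0)
  expect_equal(hounsfield_to_porosity(0), 1)
  expect_equal(hounsfield_to_porosity(500), 0.5)
  expect_equal(hounsfield_to_porosity(1700), 0)   # dense cortical bone
  expect_equal(hounsfield_to_porosity(-100), 1)
  expect_error(hounsfield_to_porosity(NaN), "finite")
})

test_that("porosity mixing reproduces the material endpoints", {
  p0 <- porosity_to_properties(0)
  expect_equal(p0$c_p, 3100)
  expect_equal(p0$alpha_p, 0.64)
  expect_equal(p0$rho, 2200)
  p1 <- porosity_to_properties(1)
  expect_equal(p1$c_p, 1480)
  expect_equal(p1$alpha_p, 25.46)
  expect_equal(p1$rho, 1000)
  ph <- porosity_to_properties(0.5)
  expect_equal(ph$c_p, 2290)
  expect_equal(ph$rho, 1600)
  expect_equal(ph$alpha_p, 0.64 + (25.46 - 0.64) * sqrt(0.5))
})

test_that("speed/density decrease and absorption increases with porosity", {
  psi <- seq(0, 1, 0.05)
  pr <- porosity_to_properties(psi)
  expect_true(all(diff(pr$c_p) < 0))
  expect_true(all(diff(pr$rho) < 0))
  expect_true(all(diff(pr$alpha_p) > 0))
  # inverting the linear density law recovers porosity
  psi_back <- (2200 - pr$rho) / (2200 - 1000)
  expect_equal(psi_back, psi, tolerance = 1e-12)
})

test_that("shear properties follow the fixed ratios inside the skull only", {
  mask <- c(TRUE, TRUE, FALSE)
  sh <- derive_shear_properties(c(3100, 2290, 1560), c(0.64, 18, 0.34), mask)
  expect_equal(sh$c_s[1], 3100 * 4 / 7)
  expect_equal(sh$alpha_s[1], 0.64 * 90 / 85)
  expect_equal(sh$c_s[3], 0)
  expect_equal(sh$alpha_s[3], 0)
})

test_that("viscoelastic conversion satisfies the Lame identities", {
  # single-voxel arithmetic oracle: mu = c_s^2 rho, lambda = c_p^2 rho - 2 mu
  cs <- 3100 * 4 / 7
  expect_equal(cs^2 * 2200, 6.9035e9, tolerance = 1e-4)
  expect_equal(3100^2 * 2200 - 2 * cs^2 * 2200, 7.335e9, tolerance = 1e-4)

  spec <- phantom_spec(outer_radius_mm = 14, thickness_mm = 3, seed = 3)
  ct <- generate_skull_phantom(spec, dims = c(36, 36, 36), spacing_mm = 1)
  maps <- build_material_maps(ct, 300)
  co <- to_viscoelastic(maps, 220e3)
  expect_equal(co$lambda + 2 * co$mu, maps$c_p^2 * maps$rho,
               tolerance = 1e-6)
  expect_equal(co$mu, maps$c_s^2 * maps$rho, tolerance = 1e-6)
  expect_true(all(co$chi >= 0) && all(co$eta >= 0))
  # fluid voxels carry no shear stiffness or shear viscosity
  fl <- !maps$skull_mask
  expect_true(all(co$mu[fl] == 0) && all(co$eta[fl] == 0))
})

test_that("map building separates skull and homogeneous background", {
  ct <- ct_volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
  maps <- suppressWarnings(build_material_maps(ct, 300))
  expect_true(all(maps$c_p == 1560) && all(maps$rho == 1030) &&
                all(maps$alpha_p == 0.34))
  expect_equal(unique(as.vector(maps$BonA)), 7.1)

  mw <- suppressWarnings(build_material_maps(ct, 300, background = "water"))
  expect_true(all(mw$c_p == 1480))
  expect_equal(unique(as.vector(mw$BonA)), 5.2)

  # threshold above the maximum HU leaves only background
  spec <- phantom_spec(outer_radius_mm = 12, thickness_mm = 2, seed = 1)
  ct2 <- generate_skull_phantom(spec, dims = c(32, 32, 32), spacing_mm = 1)
  m2 <- suppressWarnings(build_material_maps(ct2, 2000))
  expect_false(any(m2$skull_mask))
  expect_true(all(m2$c_p == 1560))

  # texture amplitude 0: a single-valued skull
  spec0 <- phantom_spec(outer_radius_mm = 12, thickness_mm = 2,
                        texture_amplitude = 0)
  ct0 <- generate_skull_phantom(spec0, dims = c(32, 32, 32), spacing_mm = 1)
  m0 <- build_material_maps(ct0, 300)
  expect_length(unique(m0$c_p[m0$skull_mask]), 1)
})
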