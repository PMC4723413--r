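test_that("phantom degenerates and determinism behave as specified", {
  # zero thickness: pure water volume
  s0 <- phantom_spec(outer_radius_mm = 20, thickness_mm = 0,
                     inner_radius_mm = 20)
  v0 <- generate_skull_phantom(s0, dims = c(24, 24, 24))
  expect_true(all(v0$voxels == 0))

  # same spec + seed -> bit-identical
  s <- phantom_spec(outer_radius_mm = 15, thickness_mm = 3, seed = 11)
  a <- generate_skull_phantom(s, dims = c(40, 40, 40))
  b <- generate_skull_phantom(s, dims = c(40, 40, 40))
  expect_identical(a$voxels, b$voxels)

  # invalid radii
  expect_error(phantom_spec(outer_radius_mm = 10, thickness_mm = 3,
                            inner_radius_mm = 9), "inconsistent")
})

test_that("phantom HU stays in [0, 1000] and porosity needs no clamping", {
  s <- phantom_spec(outer_radius_mm = 18, thickness_mm = 3, seed = 2)
  v <- generate_skull_phantom(s, dims = c(48, 48, 48))
  expect_true(all(v$voxels >= 0 & v$voxels <= 1000))
  shell <- v$voxels > 0
  psi <- 1 - v$voxels[shell] / 1000
  expect_true(all(psi >= 0 & psi <= 1))

  # constant-porosity shell for zero texture amplitude
  sc <- phantom_spec(outer_radius_mm = 18, thickness_mm = 3,
                     texture_amplitude = 0, porosity_mean = 0.4)
  vc <- generate_skull_phantom(sc, dims = c(48, 48, 48))
  expect_equal(unique(vc$voxels[vc$voxels > 0]), 600)
})

test_that("porosity texture has the requested correlation length", {
  f <- skullwave:::smooth_noise_field(c(72, 72, 72), 1, 4, seed = 5)
  # radial autocorrelation along the axes via FFT
  ac <- Re(fft(Mod(fft(f))^2, inverse = TRUE)) / length(f)
  ac <- ac / ac[1, 1, 1]
  prof <- (ac[1:15, 1, 1] + ac[1, 1:15, 1] + ac[1, 1, 1:15]) / 3
  r_e <- approx(prof, seq_along(prof) - 1, xout = exp(-1))$y
  expect_gt(r_e, 4 * 0.8)
  expect_lt(r_e, 4 * 1.2)
})

test_that("array lattice is on-sphere, complete and non-overlapping", {
  g <- generate_array(1024, 0.30, 0.005)
  expect_equal(nrow(g$centers), 1024)
  r <- sqrt(rowSums(g$centers^2))
  expect_true(all(abs(r - 0.15) < 1e-9))
  expect_true(all(g$centers[, 3] < 0))        # bowl below the focal plane
  expect_equal(sqrt(rowSums(g$normals^2)), rep(1, 1024), tolerance = 1e-12)
  # brute-force pairwise separation for the default configuration
  expect_gte(min(dist(g$centers)), 2 * g$element_radius)

  g2 <- generate_array(2, 0.30, 0.005)
  expect_equal(nrow(g2$centers), 2)
  expect_gte(min(dist(g2$centers)), 2 * g2$element_radius)

  err <- tryCatch(generate_array(1024, 0.30, 0.007), error = conditionMessage)
  expect_match(err, "maximum element radius")
  expect_match(err, "0.005")  # names the feasible radius
})

test_that("PCD geometry is placed and oriented as specified", {
  p <- generate_pcd()
  expect_equal(sqrt(sum(p$center^2)), 0.10)
  expect_equal(p$radius_of_curvature, 0.15)
  expect_equal(p$aperture_length, 0.040)
  expect_equal(p$aperture_width, 0.007)
  expect_equal(sqrt(sum(p$orientation^2)), 1, tolerance = 1e-12)
  # aimed at the focus
  expect_equal(as.numeric(p$center + 0.10 * p$orientation), c(0, 0, 0),
               tolerance = 1e-12)
  pr <- generate_pcd(side = "right")
  expect_equal(pr$center, -p$center)
})

test_that("CT volumes and geometry round-trip through disk formats", {
  s <- phantom_spec(outer_radius_mm = 12, thickness_mm = 2, seed = 4)
  v <- generate_skull_phantom(s, dims = c(24, 24, 24))
  f <- tempfile(fileext = ".nii.gz")
  write_ct_nifti(v, f)
  v2 <- read_ct_nifti(f)
  expect_identical(round(v$voxels), v2$voxels)
  expect_equal(v$spacing, v2$spacing)
  unlink(f)

  g <- generate_array(16, 0.1, 0.004)
  fy <- tempfile(fileext = ".yaml")
  write_geometry_yaml(g, fy)
  g2 <- read_geometry_yaml(fy)
  expect_equal(g$centers, g2$centers, tolerance = 1e-9)
  expect_s3_class(g2, "array_geometry")
  unlink(fy)
})
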