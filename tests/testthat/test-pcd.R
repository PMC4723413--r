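test_that("the PCD aperture is sampled on its focused spherical cap", {
  pcd <- generate_pcd()
  ap <- skullwave:::pcd_aperture_points(pcd, 0.4e-3)
  # within the aperture bounding box in the transverse plane
  rel <- sweep(ap$pts, 2, pcd$center, "-")
  b <- skullwave:::orthonormal_basis(pcd$orientation)
  u <- rel %*% b$e1; v <- rel %*% b$e2
  expect_lte(max(abs(u)), 0.020 + 1e-9)
  expect_lte(max(abs(v)), 0.0035 + 1e-9)
  # sagitta toward the curvature centre, never negative
  w <- rel %*% pcd$orientation
  expect_true(all(w >= -1e-12))
  expect_lte(max(w), 0.15 - sqrt(0.15^2 - 0.02^2) + 1e-4)
  # total area preserved by the per-point weights
  expect_equal(ap$ds * nrow(ap$pts), 0.040 * 0.007, tolerance = 1e-12)
})

test_that("sensitivity maps are normalized and focus near the curvature centre", {
  sm <- fixture("pcd_free_field", function() {
    # scaled free-field check: short-offset PCD, frequency low enough for a
    # coarse grid
    pcd <- generate_pcd(offset_from_focus = 0.04, f0 = 110e3,
                        radius_of_curvature = 0.04,
                        aperture_length = 0.03, aperture_width = 0.007)
    grid <- sim_grid(c(72, 48, 48), 2e-3, duration = 85e-6)
    maps <- uniform_maps(grid, "water")
    pcd_transmit_field(pcd, maps, grid, frequency = 110e3)
  })
  expect_equal(max(sm$map), 1)
  expect_true(all(sm$map >= 0 & sm$map <= 1))
  # peak within a few mm of the curvature centre (the geometric focus of
  # the weakly focused aperture), along the orientation axis
  m <- sm$map
  m[sm$result$source_mask_idx0 + 1] <- 0
  m[!skullwave:::interior_mask(sm$result$grid)] <- 0
  pk <- arrayInd(which.max(m), dim(m))[1, ]
  pos <- skullwave:::voxel_to_pos(sm$result$grid, pk)[1, ]
  expect_lt(abs(pos[2]), 6e-3)
  expect_lt(abs(pos[3]), 6e-3)
  # axial peak between the aperture and twice the curvature length
  expect_gt(pos[1], -0.04)
  expect_lt(pos[1], 0.05)
  # grid-resolution guard
  expect_error(pcd_transmit_field(generate_pcd(), uniform_maps(
    sim_grid(c(16, 16, 16), 2e-3, duration = 1e-6), "water"),
    sim_grid(c(16, 16, 16), 2e-3, duration = 1e-6), frequency = 610e3),
    "too coarse")
})

test_that("combined maps multiply, renormalize and commute", {
  a <- array(runif(4^3), c(4, 4, 4))
  b <- array(runif(4^3), c(4, 4, 4))
  ab <- combined_map(a, b)
  expect_equal(max(ab), 1)
  expect_equal(ab, combined_map(b, a), tolerance = 1e-12)
  # an all-ones PCD map leaves the normalized FUS field unchanged
  expect_equal(combined_map(a, array(1, dim(a))), a / max(a),
               tolerance = 1e-12)
  # disjoint supports: zero map
  a2 <- array(0, c(4, 4, 4)); a2[1, 1, 1] <- 1
  b2 <- array(0, c(4, 4, 4)); b2[4, 4, 4] <- 1
  expect_true(all(combined_map(a2, b2) == 0))
})

test_that("intersection fractions behave as set ratios", {
  f <- array(0, c(6, 6, 6)); f[2:4, 2:4, 2:4] <- 1
  expect_equal(intersection_fraction(f, f), 1)
  g <- array(0, c(6, 6, 6)); g[6, 6, 6] <- 1
  expect_equal(intersection_fraction(g, f), 0)
  # invariant under rescaling of either field
  h <- array(runif(6^3), c(6, 6, 6))
  expect_equal(intersection_fraction(3.7 * h, f),
               intersection_fraction(h, f))
  expect_equal(intersection_fraction(h, 0.2 * f),
               intersection_fraction(h, f))
  expect_error(intersection_fraction(h, array(0, c(6, 6, 6))), "empty")
  expect_error(intersection_fraction(h, array(1, c(5, 5, 5))), "grids")
})
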