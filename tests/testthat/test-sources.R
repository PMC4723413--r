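test_that("Rayleigh piston integral matches the on-axis closed form", {
  a <- 0.005
  zs <- c(0.02, 0.05, 0.15)
  p <- rayleigh_piston_field(c(0, 0, 0), c(0, 0, 1), a, 1 + 0i,
                             cbind(0, 0, zs))
  expect_equal(Mod(p), on_axis_piston(a, zs), tolerance = 0.005)
  # linear in the drive
  p2 <- rayleigh_piston_field(c(0, 0, 0), c(0, 0, 1), a, 2 + 0i,
                              cbind(0, 0, zs))
  expect_equal(p2, 2 * p, tolerance = 1e-12)
  # 1/r far-field decay beyond the Rayleigh distance
  zz <- seq(0.2, 0.8, 0.05)
  pp <- Mod(rayleigh_piston_field(c(0, 0, 0), c(0, 0, 1), a, 1 + 0i,
                                  cbind(0, 0, zz)))
  slope <- coef(lm(log(pp) ~ log(zz)))[2]
  expect_equal(as.numeric(slope), -1, tolerance = 0.02)
  # singular on the piston face
  expect_error(rayleigh_piston_field(c(0, 0, 0), c(0, 0, 1), a, 1 + 0i,
                                     cbind(0.001, 0, 0)),
               "singular")
})

test_that("steering phases conjugate the water time of flight", {
  geom <- test_array()
  # geometric centre: all elements equidistant -> equal phases
  d0 <- steering_phases(geom, c(0, 0, 0))
  expect_lt(diff(range(Arg(d0$weights))), 1e-9)
  expect_true(all(Mod(d0$weights) == 1))
  # the experimental steering offset produces finite, element-wise phases
  d1 <- steering_phases(geom, c(0.016, 0, 0.003))
  expect_true(all(is.finite(Arg(d1$weights))))
  expect_gt(diff(range(Arg(d1$weights))), 0.1)
  # a global phase constant leaves relative element phasing unchanged
  d2 <- element_drive(d1$weights * exp(1i * 0.8))
  expect_equal(Arg(d2$weights / d1$weights),
               rep(0.8, length(d1$weights)), tolerance = 1e-9)
  expect_error(steering_phases(geom, c(0.2, 0, 0)), "inside")
})

test_that("surface projection superposes element fields", {
  geom <- generate_array(8, 0.15, 0.004, f0 = 220e3)
  sspec <- surface_spec(0.06)
  one <- element_drive(c(1 + 0i, rep(0, 7)))
  surf1 <- project_to_surface(geom, one, sspec)
  # sampling contract
  lam <- 1480 / 220e3
  expect_lte(sqrt(surf1$ds), lam / 4 + 1e-9)
  rr <- sqrt(rowSums(surf1$points^2))
  expect_lt(max(abs(rr - 0.03)), 1e-9)
  # single element, unrestricted: equals that element's Rayleigh field
  direct <- rayleigh_piston_field(geom$centers[1, ], geom$normals[1, ],
                                  0.004, 1 + 0i, surf1$points)
  expect_equal(surf1$pressure, direct, tolerance = 1e-12)
  # zero drives -> zero source; additivity to 1e-10
  z <- project_to_surface(geom, element_drive(rep(0 + 0i, 8)), sspec)
  expect_true(all(Mod(z$pressure) == 0))
  wa <- complex(real = rnorm(8), imaginary = rnorm(8))
  wb <- complex(real = rnorm(8), imaginary = rnorm(8))
  sa <- project_to_surface(geom, element_drive(wa), sspec)
  sb <- project_to_surface(geom, element_drive(wb), sspec)
  sab <- project_to_surface(geom, element_drive(wa + wb), sspec)
  expect_lt(max(Mod(sab$pressure - sa$pressure - sb$pressure)) /
              max(Mod(sab$pressure)), 1e-10)
})

test_that("cross-section restriction only keeps samples near the element cone", {
  geom <- generate_array(8, 0.15, 0.004, f0 = 220e3)
  dr <- element_drive(rep(1 + 0i, 8))
  unres <- project_to_surface(geom, dr, surface_spec(0.06))
  res <- project_to_surface(geom, dr, surface_spec(0.06), restrict = TRUE)
  expect_true(res$restricted)
  # restriction removes energy, never adds it
  expect_lt(sum(Mod(res$pressure)^2), sum(Mod(unres$pressure)^2))
})

test_that("time sources start at zero and carry their grid bookkeeping", {
  g <- sim_grid(c(24, 24, 24), 2e-3, duration = 1e-5)
  src <- point_time_source(g, c(0, 0, 0), S = 10, f0 = 220e3, smooth = FALSE)
  expect_s3_class(src, "time_source")
  expect_true(all(src$idx0 >= 0 & src$idx0 < 24^3))
  # hard onset: drive is sin(omega t), zero at t = 0
  expect_equal(sin(2 * pi * src$f0 * 0), 0)
  # smoothing preserves the total injected complex amplitude (DC gain 1)
  sm <- point_time_source(g, c(0, 0, 0), S = 10, f0 = 220e3, smooth = TRUE)
  expect_equal(sum(sm$amp), sum(src$amp), tolerance = 1e-3)
})
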