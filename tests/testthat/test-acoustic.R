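test_that("linear solver output scales exactly with the source amplitude", {
  g <- sim_grid(c(32, 32, 32), 2e-3, duration = 30e-6)
  maps <- uniform_maps(g, "water")
  s1 <- point_time_source(g, c(0, 0, 0), S = 100, f0 = 220e3)
  s2 <- point_time_source(g, c(0, 0, 0), S = 200, f0 = 220e3)
  r1 <- run_acoustic(maps, s1, g, record_start = "none", absorption = "off")
  r2 <- run_acoustic(maps, s2, g, record_start = "none", absorption = "off")
  nz <- r1$pmax > max(r1$pmax) * 1e-6
  expect_lt(max(abs(r2$pmax[nz] / r1$pmax[nz] - 2)), 1e-10)
})

test_that("free-field amplitude follows the 1/r Green's function", {
  gr <- green_run()
  # far-field halving over a doubled distance (sensors at 20 and 40 mm)
  expect_equal(gr$a2 / gr$a1, 0.5, tolerance = 0.02)
  # absolute calibration against the analytic monopole
  expect_equal(gr$a1, Mod(monopole_field(0.02, strength = 1000)),
               tolerance = 0.02)
})

test_that("plane-wave transmission is exact for identical media", {
  r <- measure_plane_wave_transmission(1480, 1000, 1480, 1000,
                                       spacing = 2e-3, f0 = 220e3, nx = 240)
  expect_lt(r$rel_error, 0.005)
  expect_equal(r$T_analytic, 1)
})

test_that("lossless homogeneous runs conserve acoustic energy", {
  g <- sim_grid(c(32, 32, 32), 3e-3, duration = 260e-6,
                pml_size = 0, pml_alpha = 0)
  maps <- uniform_maps(g, "water")
  src <- point_time_source(g, c(0, 0, 0), S = 1000, f0 = 220e3)
  src$stop_time <- 10 / 220e3          # switch the source off after 10 cycles
  res <- run_acoustic(maps, src, g, record_start = "none",
                      absorption = "off", energy = TRUE)
  # 50 periods after switch-off, with periodic wrap instead of a PML
  per <- ceiling(1 / (220e3 * res$dt))
  i0 <- ceiling((src$stop_time + 5e-6) / res$dt)
  i1 <- min(res$nt - per, i0 + ceiling(50 / 220e3 / res$dt))
  # cycle-averaged energy: kinetic and potential samples live on staggered
  # time points, so the instantaneous sum carries a 2f0 ripple
  e0 <- mean(res$energy[i0:(i0 + per)])
  e1 <- mean(res$energy[i1:(i1 + per)])
  expect_gt(e0, 0)
  expect_lt(abs(e1 - e0) / e0, 0.01)
})

test_that("heterogeneous lossless propagation is reciprocal", {
  g <- sim_grid(c(48, 48, 48), 2e-3, duration = 60e-6)
  # smooth lossless speed/density heterogeneity between the two points
  axv <- skullwave:::grid_axis(g, 1)
  bump <- outer(outer(exp(-(axv)^2 / (2 * 0.015^2)),
                      exp(-(axv)^2 / (2 * 0.015^2))),
                exp(-(axv - 0.005)^2 / (2 * 0.015^2)))
  maps <- uniform_maps(g, "water")
  maps$c_p <- array(1480 * (1 + 0.25 * bump), g$dims)
  maps$rho <- array(1000 * (1 + 0.15 * bump), g$dims)
  A <- c(-0.025, 0, -0.012); B <- c(0.022, 0.008, 0.015)
  sAB <- run_acoustic(maps, point_time_source(g, A, S = 1000, f0 = 220e3),
                      g, sensors = matrix(B, 1), record_start = "none",
                      absorption = "off")
  sBA <- run_acoustic(maps, point_time_source(g, B, S = 1000, f0 = 220e3),
                      g, sensors = matrix(A, 1), record_start = "none",
                      absorption = "off")
  aAB <- skullwave:::steady_amplitude(sAB$traces[, 1], sAB$dt, 220e3, 6)
  aBA <- skullwave:::steady_amplitude(sBA$traces[, 1], sBA$dt, 220e3, 6)
  expect_equal(aAB / aBA, 1, tolerance = 0.01)
})

test_that("the focal spot does not move under a 90-degree grid rotation", {
  g <- sim_grid(c(48, 48, 48), 2e-3, duration = 55e-6)
  maps <- uniform_maps(g, "water")
  # converging cap along -z, then the same cap rotated to -x
  n <- 80; i <- seq_len(n)
  cz <- -(i - 0.5) / n * 0.45 - 0.5
  st <- sqrt(pmax(0, 1 - cz^2)); phi <- pi * (3 - sqrt(5)) * i
  pts <- 0.035 * cbind(st * cos(phi), st * sin(phi), cz)
  k <- 2 * pi * 220e3 / 1480
  S <- 1000 * exp(-1i * k * sqrt(rowSums(pts^2)))
  rot <- pts[, c(3, 2, 1)]                    # swap x and z
  r1 <- run_acoustic(maps, skullwave:::monopole_time_source(
    g, pts, S, 220e3, target = c(0, 0, 0)), g, record_start = 42e-6,
    absorption = "off")
  r2 <- run_acoustic(maps, skullwave:::monopole_time_source(
    g, rot, S, 220e3, target = c(0, 0, 0)), g, record_start = 42e-6,
    absorption = "off")
  p1 <- arrayInd(which.max(r1$pmax), g$dims)[1, ]
  p2 <- arrayInd(which.max(r2$pmax), g$dims)[1, ]
  expect_lte(max(abs(p1 - p2[c(3, 2, 1)])), 1)
})

test_that("power-law absorption attenuates at the mapped rate", {
  nx <- 400; dims <- c(nx, 1, 1)
  # duration covers arrival at the far sensor (103 us) plus the ramp and
  # a clean 8-cycle fitting window
  g <- sim_grid(dims, 1e-3, duration = 210e-6)
  maps <- structure(list(c_p = array(3100, dims), rho = array(2200, dims),
                         alpha_p = array(5, dims), BonA = array(0, dims)),
                    class = "material_maps")
  src <- skullwave:::raw_time_source(
    g, skullwave:::voxel_to_pos(g, c(30, 1, 1)), 1 + 0i, 220e3)
  sens <- rbind(skullwave:::voxel_to_pos(g, c(150, 1, 1)),
                skullwave:::voxel_to_pos(g, c(350, 1, 1)))
  run <- run_acoustic(maps, src, g, sensors = sens,
                      record_start = "none", absorption = "on")
  a1 <- skullwave:::steady_amplitude(run$traces[, 1], run$dt, 220e3, 8)
  a2 <- skullwave:::steady_amplitude(run$traces[, 2], run$dt, 220e3, 8)
  # 5 dB/(MHz cm) at 220 kHz over 200 mm
  alpha_np <- 5 * 0.22 * 100 * log(10) / 20
  expect_equal(log(a2 / a1), -alpha_np * 0.2, tolerance = 0.12)
})

test_that("nonlinear mode converges to the linear field at low amplitude", {
  nx <- 240
  g <- sim_grid(c(nx, 1, 1), 1e-3, duration = 120e-6)
  maps <- structure(list(c_p = array(1480, c(nx, 1, 1)),
                         rho = array(1000, c(nx, 1, 1)),
                         alpha_p = array(0, c(nx, 1, 1)),
                         BonA = array(5.2, c(nx, 1, 1))),
                    class = "material_maps")
  sensor <- skullwave:::voxel_to_pos(g, c(180, 1, 1))
  reldiff <- function(amp) {
    src <- skullwave:::raw_time_source(
      g, skullwave:::voxel_to_pos(g, c(40, 1, 1)), amp + 0i, 220e3)
    lin <- run_acoustic(maps, src, g, sensors = sensor,
                        record_start = "none", absorption = "off")
    nl <- run_acoustic(maps, src, g, sensors = sensor,
                       record_start = "none", absorption = "off",
                       mode = "nonlinear")
    max(abs(nl$traces - lin$traces)) / max(abs(lin$traces))
  }
  lo <- reldiff(1e-4)
  hi <- reldiff(10)
  expect_lt(lo, 1e-6)
  expect_gt(hi, 100 * lo)
})
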