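# Shared fixtures for the test suite.  Expensive simulations are built
# lazily and cached for the whole test run (several files assert different
# properties of the same field).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

water <- function() list(c = 1480, rho = 1000)

# small scaled array used by source/aberration tests: 128 elements on a
# 15 cm hemisphere (same f-number as the full device, fewer elements)
test_array <- function() generate_array(128, 0.15, 0.004, f0 = 220e3)

# focused monopole cap: a cheap converging source entirely inside a grid
cap_source <- function(grid, radius = 0.04, n = 120, f0 = 220e3,
                       amp = 1000, focus = c(0, 0, 0)) {
  i <- seq_len(n)
  cz <- -(i - 0.5) / n * 0.45 - 0.5
  st <- sqrt(pmax(0, 1 - cz^2))
  phi <- pi * (3 - sqrt(5)) * i
  pts <- radius * cbind(st * cos(phi), st * sin(phi), cz)
  pts <- sweep(pts, 2, focus, "+")
  k <- 2 * pi * f0 / 1480
  r0 <- sqrt(rowSums(sweep(pts, 2, focus, "-")^2))
  S <- amp * exp(-1i * k * r0)
  skullwave:::monopole_time_source(grid, pts, S, f0, target = focus)
}

# aberrating skull phantom scenario shared by the correction tests:
# a small array inside the grid, a thin textured skull shell around the
# target, acoustic solver
aberration_fixture <- function() {
  fixture("aberration", function() {
    f0 <- 220e3
    geom <- generate_array(96, 0.075, 0.003, f0 = f0)
    grid <- sim_grid(c(80, 80, 80), 1.4e-3, duration = 75e-6)
    spec <- phantom_spec(outer_radius_mm = 26, thickness_mm = 3.5,
                         porosity_mean = 0.35, texture_amplitude = 0.25,
                         texture_corr_mm = 5, seed = 7)
    ct <- generate_skull_phantom(spec, dims = grid$dims, spacing_mm = 1.4)
    maps <- build_material_maps(ct, skull_hu_threshold = 300)
    target <- c(0.004, 0, 0.002)
    corr <- measure_corrections(maps, geom, target, grid)
    list(f0 = f0, geom = geom, grid = grid, maps = maps, target = target,
         corr = corr)
  })
}

# free-space Green's-function run shared by the oracle checks
green_run <- function() {
  fixture("green_run", function() {
    g <- sim_grid(c(120, 72, 72), 1.25e-3, duration = 82e-6)
    maps <- uniform_maps(g, "water")
    src <- point_time_source(g, c(-0.04, 0, 0), S = 1000, f0 = 220e3)
    res <- run_acoustic(maps, src, g,
                        sensors = rbind(c(-0.02, 0, 0), c(0, 0, 0)),
                        record_start = "none", absorption = "off")
    a1 <- skullwave:::steady_amplitude(res$traces[, 1], res$dt, 220e3, 6)
    a2 <- skullwave:::steady_amplitude(res$traces[, 2], res$dt, 220e3, 6)
    list(a1 = a1, a2 = a2)
  })
}

# matched-discretization water runs for the elastic fluid-limit check
fluid_limit_pair <- function() {
  fixture("fluid_limit_pair", function() {
    grid <- sim_grid(c(48, 48, 48), 2e-3, duration = 60e-6, cfl = 0.2)
    maps <- uniform_maps(grid, "water")
    src <- cap_source(grid, radius = 0.034, n = 100)
    ra <- run_acoustic(maps, src, grid, record_start = 45e-6,
                       absorption = "off", kspace_correction = FALSE)
    re <- run_elastic(to_viscoelastic(maps, 220e3), src, grid,
                      record_start = 45e-6)
    list(acoustic = ra, elastic = re)
  })
}

# Table-II-scale water-only steered run of the full 1024-element device
water_reference_run <- function() {
  fixture("water_reference", function() {
    cfg <- run_config(phantom = NULL,
                      grid_dims = c(144, 144, 108), spacing_mm = 1,
                      grid_origin_mm = c(-71.5, -71.5, -78),
                      duration_us = 120,
                      steering_mm = c(16, 0, 3),
                      solver = "acoustic")
    run_scenario(cfg)
  })
}

# Huygens-reduction verification pair: the full scaled array simulated
# directly vs its reduced surface-source equivalent, same spacing
huygens_pair <- function() {
  fixture("huygens_pair", function() {
    geom <- test_array()
    target <- c(0.004, 0, 0.002)
    dr <- steering_phases(geom, target)
    gf <- sim_grid(c(108, 108, 72), 2e-3, duration = 134e-6,
                   origin = c(-107e-3, -107e-3, -102e-3))
    full <- run_acoustic(uniform_maps(gf, "water"),
                         piston_time_source(gf, geom, dr, target = target),
                         gf, record_start = 122e-6, absorption = "off")
    gr <- sim_grid(c(60, 60, 60), 2e-3, duration = 95e-6)
    surf <- project_to_surface(geom, dr, surface_spec(0.05))
    red <- run_acoustic(uniform_maps(gr, "water"),
                        surface_to_time_source(surf, gr, target = target),
                        gr, record_start = 80e-6, absorption = "off")
    list(full = full, reduced = red, target = target)
  })
}

# lateral first-sidelobe level of a focal field: interpolate around the
# peak, take the in-plane (perpendicular to the beam axis) radial max
# profile through the peak, find the null ring and the maximum beyond it.
# The shell-max profile over full spheres is monotone (the axial lobe is
# long), so the ring structure must be measured laterally.
first_sidelobe_lateral <- function(result, half_extent = 8e-3) {
  pk <- focal_peak(result)
  ff <- interpolate_focus(result, center = pk$position,
                          half_extent = half_extent, resolution = 0.5e-3)
  ax <- lapply(1:3, function(d)
    ff$origin[d] + (seq_len(ff$dims[d]) - 1) * ff$spacing)
  s2 <- outer((ax[[1]] - pk$position[1])^2,
              (ax[[2]] - pk$position[2])^2, "+")
  kz <- which(abs(ax[[3]] - pk$position[3]) <= 0.26e-3)
  slab <- ff$field[, , kz, drop = FALSE]
  prof <- sapply(seq(0.5e-3, half_extent - 0.5e-3, 0.5e-3), function(r) {
    sel <- s2 >= (r - 0.5e-3)^2 & s2 < r^2
    max(apply(slab, 3, function(m) max(m[sel]))) / pk$value
  })
  i_null <- which(diff(prof) > 0)[1]
  list(level = max(prof[(i_null + 1):length(prof)]),
       profile = prof, peak = pk$value)
}

# scaled phantom + PCD sensitivity scenario at the two detection
# frequencies, plus the therapy field, all on one lambda(610 kHz)/6 grid
pcd_scenario <- function() {
  fixture("pcd_scenario", function() {
    # duration leaves ~11 us of recording after the domain crossing:
    # more than a full period even at the 110 kHz subharmonic, so the
    # recorded per-voxel maximum is the envelope at both frequencies
    grid <- sim_grid(c(72, 72, 72), 0.4e-3, duration = 31e-6,
                     pml_size = 6)
    spec <- phantom_spec(outer_radius_mm = 7, thickness_mm = 1.6,
                         porosity_mean = 0.35, texture_amplitude = 0.15,
                         texture_corr_mm = 2, seed = 9)
    ct <- generate_skull_phantom(spec, dims = grid$dims, spacing_mm = 0.4)
    maps <- build_material_maps(ct, 300)
    pcd <- generate_pcd(offset_from_focus = 0.010, f0 = 610e3,
                        radius_of_curvature = 0.0105,
                        aperture_length = 0.0075, aperture_width = 0.002)
    s610 <- pcd_transmit_field(pcd, maps, grid, frequency = 610e3)
    s110 <- pcd_transmit_field(pcd, maps, grid, frequency = 110e3)
    fus <- run_acoustic(maps, cap_source(grid, radius = 0.010, n = 450,
                                         f0 = 220e3),
                        grid, record_start = "crossing")
    list(s610 = s610, s110 = s110, fus = fus)
  })
}

# forward run of the aberration scenario for a given correction scheme
aberration_run <- function(scheme) {
  fixture(paste0("aberration_run_", scheme), function() {
    fx <- aberration_fixture()
    drives <- steering_phases(fx$geom, fx$target)
    if (scheme != "none")
      drives <- apply_correction(drives, fx$corr, scheme)
    # the small array lies inside the grid: drive the piston faces directly
    src <- piston_time_source(fx$grid, fx$geom, drives, target = fx$target)
    run_acoustic(fx$maps, src, fx$grid, record_start = 55e-6)
  })
}
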