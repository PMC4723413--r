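#!/usr/bin/env Rscript
# Nonlinear (B/A) propagation at the treatment amplitude: linear vs
# nonlinear fields and the second-harmonic level at the focus.  The drive
# is scaled so the focal pressure is near the experimental 561 kPa, and
# the run is lengthened to sharpen the spectral lines.

rootdir <- normalizePath(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), ".."))
source(file.path(rootdir, "analysis", "00_common.R"))

target <- c(10, 0, 3) * 1e-3
cfgL <- scaled_config(sensors = matrix(target, 1), duration_us = 160)
outL <- run_scenario(cfgL)
peakL <- outL$metrics$peak_Pa
scale_drive <- 561e3 / peakL
message(sprintf("linear focal peak %.3g Pa; drive scale to 561 kPa: %.3g",
                peakL, scale_drive))

# rebuild the drive at treatment amplitude and rerun nonlinearly: the
# element weights are scaled, everything else identical
cfgN <- cfgL
cfgN$nonlinear <- TRUE
cfgN$array_args <- list(seed = 0)
# weight scaling enters through the source strength: run the scenario at
# unit drive and exploit solver linearity is not valid here, so rerun with
# scaled drives via the pipeline's amplitude hook
grid <- sim_grid(cfgN$grid_dims, cfgN$spacing_mm * 1e-3,
                 duration = cfgN$duration_us * 1e-6)
ct <- generate_skull_phantom(base_phantom, dims = cfgN$grid_dims,
                             spacing_mm = cfgN$spacing_mm)
maps <- build_material_maps(ct, 300)
geom <- generate_array()
drives <- steering_phases(geom, target)
drives$weights <- drives$weights * scale_drive
surf <- project_to_surface(geom, drives, surface_spec(0.08))
src <- surface_to_time_source(surf, grid, target = target)
resN <- run_acoustic(maps, src, grid, mode = "nonlinear",
                     sensors = matrix(target, 1))
resL <- run_acoustic(maps, src, grid, mode = "linear",
                     sensors = matrix(target, 1))

h <- harmonic_spectrum(resN$traces[, 1], resN$dt, 220e3,
                       analysis_window = 25 / 220e3)
hl <- harmonic_spectrum(resL$traces[, 1], resL$dt, 220e3,
                        analysis_window = 25 / 220e3)
df <- data.frame(focal_peak_Pa = max(focal_peak(resN)$value),
                 fundamental_Pa = h$A1, second_harmonic_Pa = h$A2,
                 ratio_db = h$ratio_db, linear_floor_db = hl$ratio_db,
                 field_max_ratio = max(resN$pmax) / max(resL$pmax))
print(df)
message(sprintf("second harmonic %.1f dB below the fundamental", -h$ratio_db))
write_table(df, "nonlinear_harmonics.csv")
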