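#!/usr/bin/env Rscript
# PCD sensitivity mapping by reciprocity at the resonant (610 kHz) and
# subharmonic (110 kHz) frequencies, combined with the therapy field to
# give the fraction of the -6 dB focal volume the detector actually sees.
# Runs on a lambda(610)/6 sub-grid around a reduced-scale head, with the
# detector aimed at the focus from the side.

rootdir <- normalizePath(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), ".."))
source(file.path(rootdir, "analysis", "00_common.R"))

grid <- sim_grid(c(96, 96, 96), 0.4e-3, duration = 34e-6, pml_size = 8)
spec <- phantom_spec(outer_radius_mm = 10, thickness_mm = 2,
                     porosity_mean = 0.3, texture_amplitude = 0.15,
                     texture_corr_mm = 2.5, seed = seed)
ct <- generate_skull_phantom(spec, dims = grid$dims, spacing_mm = 0.4)
maps <- build_material_maps(ct, 300)

pcd <- generate_pcd(offset_from_focus = 0.0135, f0 = 610e3,
                    radius_of_curvature = 0.0145,
                    aperture_length = 0.009, aperture_width = 0.0025)
message("PCD transmit field at 610 kHz ...")
s610 <- pcd_transmit_field(pcd, maps, grid, frequency = 610e3)
message("PCD transmit field at 110 kHz ...")
s110 <- pcd_transmit_field(pcd, maps, grid, frequency = 110e3)

# therapy field: converging 220 kHz cap through the phantom
cap <- local({
  n <- 1200; i <- seq_len(n)
  cz <- -(i - 0.5) / n * 0.45 - 0.5
  st <- sqrt(pmax(0, 1 - cz^2)); phi <- pi * (3 - sqrt(5)) * i
  pts <- 0.017 * cbind(st * cos(phi), st * sin(phi), cz)
  k <- 2 * pi * 220e3 / 1480
  S <- 1000 * exp(-1i * k * sqrt(rowSums(pts^2)))
  skullwave:::monopole_time_source(grid, pts, S, 220e3, target = c(0, 0, 0))
})
message("therapy field ...")
fus <- run_acoustic(maps, cap, grid, record_start = "crossing")

f610 <- intersection_fraction(combined_map(fus, s610), fus)
f110 <- intersection_fraction(combined_map(fus, s110), fus)
df <- data.frame(frequency_kHz = c(610, 110),
                 intersection_fraction = c(f610, f110))
print(df)
message(sprintf("-6 dB focal coverage: %.0f%% at 610 kHz, %.0f%% at 110 kHz",
                100 * f610, 100 * f110))
write_table(df, "pcd_sensitivity.csv")
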