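# Shared configuration for the analysis scripts: a desk-scale version of
# the study geometry.  The device (1024-element, 30 cm hemisphere, 220 kHz)
# is full size; the cranium phantom (~5 cm) and the grid (96^3 at 1.4 mm)
# are scaled so each scenario runs in minutes on one CPU.  The methods
# vignette discusses what does and does not transfer from this scale.

library(skullwave)

res_dir <- file.path(rootdir, "results")
dir.create(res_dir, showWarnings = FALSE)

seed <- 1

base_phantom <- phantom_spec(outer_radius_mm = 26, thickness_mm = 3.5,
                             porosity_mean = 0.3, texture_amplitude = 0.15,
                             texture_corr_mm = 4,
                             base_plate_z_mm = -6,
                             base_plate_thickness_mm = 3,
                             seed = seed)

scaled_config <- function(...) {
  defaults <- list(phantom = base_phantom,
                   grid_dims = c(96, 96, 96), spacing_mm = 1.4,
                   duration_us = 65,
                   surface_diameter = 0.08,
                   steering_mm = c(10, 0, 3),
                   seed = seed)
  do.call(run_config, utils::modifyList(defaults, list(...)))
}

write_table <- function(df, name) {
  path <- file.path(res_dir, name)
  write.csv(df, path, row.names = FALSE)
  message("wrote ", path)
  df
}
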