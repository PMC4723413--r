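#!/usr/bin/env Rscript
# Water-only reference beam of the steered 1024-element hemisphere:
# the simulation behind the "no skull" row of the beam-volume table
# (-3.5 / -7 dB main beam, -12 / -14 dB side-lobe extent).

rootdir <- normalizePath(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), ".."))
source(file.path(rootdir, "analysis", "00_common.R"))

cfg <- run_config(phantom = NULL,
                  grid_dims = c(144, 144, 108), spacing_mm = 1,
                  grid_origin_mm = c(-71.5, -71.5, -78),
                  duration_us = 120,
                  steering_mm = c(16, 0, 3),
                  solver = "acoustic", seed = seed)
message("running the full-scale water beam (this is the long run) ...")
out <- run_scenario(cfg)
print(out$metrics)
write_table(out$metrics, "water_beam_metrics.csv")
saveRDS_path <- file.path(rootdir, "scratch", "water_beam.rds")
dir.create(dirname(saveRDS_path), showWarnings = FALSE)
saveRDS(out$result, saveRDS_path)   # scratch only: reused by later scripts
message("field cached under scratch/ for the comparison scripts")
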