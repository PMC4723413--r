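#!/usr/bin/env Rscript
# Aberration-correction schemes on the skull phantom: phase-only, phase +
# amplitude (focal equalization with 2x-mean clipping) and phase + inverse
# amplitude, all at constant total array power.

rootdir <- normalizePath(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), ".."))
source(file.path(rootdir, "analysis", "00_common.R"))

schemes <- c("none", "phase", "phase_amplitude", "phase_inverse_amplitude")
rows <- NULL
for (sch in schemes) {
  message("scheme: ", sch)
  out <- run_scenario(scaled_config(correction = sch))
  rows <- rbind(rows, cbind(scheme = sch, out$metrics))
}
rows$norm_peak <- rows$peak_Pa / max(rows$peak_Pa)
print(rows[, c("scheme", "norm_peak", "vol_3.5dB_mm3", "vol_14dB_mm3")])
write_table(rows, "aberration_correction.csv")
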