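#!/usr/bin/env Rscript
# Effect of the skull base on the field: the same phantom scenario with
# and without the flat base plate below the target.

rootdir <- normalizePath(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), ".."))
source(file.path(rootdir, "analysis", "00_common.R"))

with_base <- run_scenario(scaled_config(solver = "elastic"))
no_base <- run_scenario(scaled_config(solver = "elastic",
                                      remove_skull_base = TRUE),
                        reference = with_base$result)

rows <- rbind(cbind(configuration = "with skull base", with_base$metrics),
              cbind(configuration = "skull base removed", no_base$metrics))
print(rows[, c("configuration", "peak_Pa", "shift_mm",
               "vol_3.5dB_mm3", "vol_7dB_mm3", "vol_12dB_mm3")])
cmp <- compare_runs(no_base$result, with_base$result)
message(sprintf("peak ratio %.3f; -3.5 dB volume ratio %.3f",
                cmp$peak_ratio, cmp$vol_3.5dB_ratio))
write_table(rows, "skull_base.csv")
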