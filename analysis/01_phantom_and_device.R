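#!/usr/bin/env Rscript
# Generates the synthetic skull phantom and the device geometry, writes
# them to standard formats (NIfTI-1, YAML) and summarizes the material
# distribution the porosity model induces.

rootdir <- normalizePath(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), ".."))
source(file.path(rootdir, "analysis", "00_common.R"))

# volumes and full geometry listings are bulky; they go under scratch/
# while the summary table lands in results/
out_dir <- file.path(rootdir, "scratch")
dir.create(out_dir, showWarnings = FALSE)
ct <- generate_skull_phantom(base_phantom, dims = c(96, 96, 96),
                             spacing_mm = 1.4)
write_ct_nifti(ct, file.path(out_dir, "phantom_ct.nii.gz"))
message("phantom CT written: ", paste(dim(ct$voxels), collapse = "x"),
        " voxels at 1.4 mm")

geom <- generate_array()
write_geometry_yaml(geom, file.path(out_dir, "array_geometry.yaml"))
pcd <- generate_pcd()
write_geometry_yaml(pcd, file.path(res_dir, "pcd_geometry.yaml"))

maps <- build_material_maps(ct, skull_hu_threshold = 300)
sk <- maps$skull_mask
summary_df <- data.frame(
  skull_voxels = sum(sk),
  skull_volume_cm3 = sum(sk) * 1.4^3 / 1e3,
  mean_c_p = mean(maps$c_p[sk]),
  mean_rho = mean(maps$rho[sk]),
  mean_alpha_p = mean(maps$alpha_p[sk]),
  mean_c_s = mean(maps$c_s[sk]),
  hu_min = min(ct$voxels[sk]), hu_max = max(ct$voxels[sk]),
  min_element_gap_mm = min(dist(geom$centers)) * 1e3
)
print(t(summary_df))
write_table(summary_df, "phantom_summary.csv")
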