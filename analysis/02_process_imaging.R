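#!/usr/bin/env Rscript
# Run the imaging pipeline (screening, registration, segmentation,
# diametry, velocimetry, hemodynamics) over the sequences produced by
# 01_simulate_scenes.R and compare recovered diameters/velocities against
# the rendered ground truth.

suppressMessages(library(conjflow))

scene_dir <- "results/scenes"
out <- "results/imaging"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

subjects <- read.csv(file.path(scene_dir, "subjects.csv"))
truth <- read.csv(file.path(scene_dir, "ground_truth.csv"))

seqs <- setNames(
  as.list(file.path(scene_dir, paste0(subjects$subject_id, ".tif"))),
  subjects$subject_id
)
res <- run_pipeline(seqs, subjects, pipeline_config(), out_dir = out)
vessels <- res$vessels

# match measured vessels to ground truth by subject and nearest diameter
matched <- do.call(rbind, lapply(seq_len(nrow(vessels)), function(i) {
  tr <- truth[truth$subject_id == vessels$subject_id[i], ]
  j <- which.min(abs(tr$d_true_um - vessels$d_um[i]))
  data.frame(vessels[i, c("subject_id", "vessel_id", "d_um", "v_mm_s")],
             d_true_um = tr$d_true_um[j], v_true_mm_s = tr$v_true_mm_s[j])
}))
matched$d_err_um <- matched$d_um - matched$d_true_um
matched$v_rel_err <- abs(matched$v_mm_s - matched$v_true_mm_s) /
  matched$v_true_mm_s
write.csv(matched, file.path(out, "recovery_vs_truth.csv"),
          row.names = FALSE)

cat(sprintf("measured %d vessels across %d subjects\n", nrow(vessels),
            length(unique(vessels$subject_id))))
cat(sprintf("diameter error: mean %.2f um, MAE %.2f um (max |err| %.2f)\n",
            mean(matched$d_err_um), mean(abs(matched$d_err_um)),
            max(abs(matched$d_err_um))))
cat(sprintf("velocity relative error: median %.1f%%, 90th pct %.1f%%\n",
            100 * median(matched$v_rel_err, na.rm = TRUE),
            100 * quantile(matched$v_rel_err, 0.9, na.rm = TRUE)))
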