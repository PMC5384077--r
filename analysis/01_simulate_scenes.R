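#!/usr/bin/env Rscript
# Generate the synthetic imaging study: four subjects per DR stage group,
# each with one field of parallel microvessels of known diameter and
# velocity, written as multi-page TIFF plus ground-truth CSV. Later
# scripts consume these files, so the whole analysis is reproducible from
# a single seed.

suppressMessages(library(conjflow))

seed <- 20260925
out <- "results/scenes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

groups <- rep(c("C", "NDR", "NPDR", "PDR"), each = 2)
n_subjects <- length(groups)

make_scene <- function(i) {
  set.seed(seed + i)
  vlist <- lapply(1:5, function(k) {
    vessel_spec(
      cbind(c(20, 260), rep(35 + (k - 1) * 45, 2)),
      diameter_um = runif(1, 8, 30),
      velocity_mm_s = runif(1, 0.15, 1.8),
      type = sample(c("arteriole", "venule"), 1, prob = c(0.2, 0.8))
    )
  })
  scene_spec(280, 220, vessels = vlist, noise_sd = 0.02,
             jitter_amplitude_px = 1.2, blink_frames = if (i %% 3 == 0) 1:3
             else integer(0))
}

set.seed(seed)
subjects <- data.frame(
  subject_id = sprintf("P%02d", seq_len(n_subjects)),
  group = groups,
  age = round(rnorm(n_subjects, c(61, 61, 55, 55, 58, 58, 53, 53), 8)),
  sex = sample(c("F", "M"), n_subjects, replace = TRUE),
  race = sample(c("AA", "White", "Hispanic"), n_subjects, replace = TRUE),
  map = round(rnorm(n_subjects, 91, 10)),
  hr = round(rnorm(n_subjects, 74, 9)),
  hct = round(rnorm(n_subjects, c(0.44, 0.44, 0.42, 0.42, 0.40, 0.40,
                                  0.37, 0.37), 0.03), 3),
  hba1c = round(rnorm(n_subjects, c(5.5, 5.5, 7.4, 7.4, 8.4, 8.4, 8.2,
                                    8.2), 0.6), 1)
)
write.csv(subjects, file.path(out, "subjects.csv"), row.names = FALSE)

truths <- list()
for (i in seq_len(n_subjects)) {
  r <- render_sequence(make_scene(i), seed = seed + 100 + i)
  sid <- subjects$subject_id[i]
  write_sequence_tiff(r$sequence, file.path(out, paste0(sid, ".tif")))
  tr <- r$truth
  tr$subject_id <- sid
  truths[[i]] <- tr
  cat(sprintf("%s: %d vessels, %d blink frames\n", sid, nrow(tr),
              length(make_scene(i)$blink_frames)))
}
truth <- do.call(rbind, truths)
write.csv(truth, file.path(out, "ground_truth.csv"), row.names = FALSE)

cat(sprintf("wrote %d sequences, %d true vessels to %s\n",
            n_subjects, nrow(truth), out))
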