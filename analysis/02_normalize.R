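#!/usr/bin/env Rscript
# Stage 2: object-centered normalization and time normalization.
#
# For each trial, fit the seat-surface and backrest planes of its scan,
# build the seat-anchored basis (origin at the armrest/handrail base, z up,
# x front-back), re-express the skeleton in that frame, and resample to the
# common 500-frame clock. Works purely from the files stage 1 wrote — no
# generator ground truth is consulted.

library(stsmap)

out <- "results/analysis"
tdir <- file.path(out, "trials")
meta <- read_metadata_tsv(file.path(out, "metadata.tsv"))

for (id in meta$trial_id) {
  scan <- read_seat_scan(file.path(tdir, paste0(id, "_scan.json")))
  seqc <- read_skeleton_csv(file.path(tdir, paste0(id, "_camera.csv")))
  frame <- object_frame_from_scan(scan, skeleton_hint = seqc)
  rs <- resample_sequence(normalize_sequence(seqc, frame), n_out = 500)
  write_object_frame_json(frame, file.path(tdir, paste0(id, "_frame.json")))
  write_skeleton_csv(rs, file.path(tdir, paste0(id, "_object_resampled.csv")))
}

cat(sprintf("normalized and resampled %d trials to 500 frames\n", nrow(meta)))
cat("object frames and resampled skeletons written under", tdir, "\n")
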