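#!/usr/bin/env Rscript
# Stage 1: simulate the 24-trial sit-to-stand library.
#
# One trial per row of the study composition table: a seat scan (surface +
# backrest/side-frame patches, anchor annotation) under a random
# ceiling-camera pose, and a camera-frame 13-joint skeleton sequence.
# Trials no31_4 and no32_2 carry the forward-lean archetype, the rest are
# armrest-assisted. Everything is written as plain text for the next stages.

library(stsmap)

seed <- 1L
out <- "results/analysis"
tdir <- file.path(out, "trials")
dir.create(tdir, recursive = TRUE, showWarnings = FALSE)

lib <- simulate_library(seed = seed)
write_metadata_tsv(lib$metadata, file.path(out, "metadata.tsv"))

for (id in names(lib$trials)) {
  write_skeleton_csv(lib$trials[[id]]$sequence,
                     file.path(tdir, paste0(id, "_camera.csv")))
  write_seat_scan(lib$trials[[id]]$scan, tdir, name = id)
}

cat(sprintf("simulated %d trials (seed %d): %s\n",
            nrow(lib$metadata), seed,
            paste(sprintf("%s x%d", names(table(lib$metadata$product)),
                          table(lib$metadata$product)), collapse = ", ")))
cat(sprintf("forward-lean trials: %s\n",
            paste(lib$metadata$trial_id[lib$metadata$archetype == "forward_lean"],
                  collapse = ", ")))
cat("wrote", file.path(out, "metadata.tsv"), "and", tdir, "\n")
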