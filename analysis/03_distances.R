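#!/usr/bin/env Rscript
# Stage 3: behavior dissimilarity.
#
# Per joint, the Manhattan distance between 500-frame object-frame
# trajectories of every trial pair (13 matrices Dj); their sum Dsum is the
# overall behavior dissimilarity used for clustering and mapping.

library(stsmap)

out <- "results/analysis"
tdir <- file.path(out, "trials")
meta <- read_metadata_tsv(file.path(out, "metadata.tsv"))

resampled <- lapply(meta$trial_id, function(id) {
  read_skeleton_csv(file.path(tdir, paste0(id, "_object_resampled.csv")),
                    coordinate_frame = "object")
})

D <- distance_matrix(resampled)
write_matrix_csv(D$total, file.path(out, "Dsum.csv"))
jdir <- file.path(out, "per_joint")
dir.create(jdir, showWarnings = FALSE)
for (j in names(D$per_joint)) {
  write_matrix_csv(D$per_joint[[j]], file.path(jdir, paste0("D_", j, ".csv")))
}

off <- D$total[upper.tri(D$total)]
cat(sprintf("Dsum over %d trials: range %.1f-%.1f m, median %.1f m\n",
            nrow(D$total), min(off), max(off), median(off)))
cat("wrote", file.path(out, "Dsum.csv"), "and 13 per-joint matrices\n")
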