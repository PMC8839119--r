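#!/usr/bin/env Rscript
# Stage 4: hierarchical clustering with silhouette model selection, and the
# cluster-average motions.
#
# UPGMA on Dsum, cut at the k (scanned 2..12) maximizing the mean silhouette;
# Ward linkage is run alongside as a robustness check. Each cluster is
# summarized by the elementwise mean of its members' trajectories.

library(stsmap)

out <- "results/analysis"
tdir <- file.path(out, "trials")
meta <- read_metadata_tsv(file.path(out, "metadata.tsv"))
Dsum <- read_matrix_csv(file.path(out, "Dsum.csv"))

tree <- behavior_linkage(Dsum, method = "upgma")
model <- select_k(tree, Dsum)
write_linkage_csv(tree, file.path(out, "linkage.csv"))
export_newick(tree, file.path(out, "dendrogram.nwk"))
write.table(data.frame(trial_id = names(model$labels),
                       cluster = unname(model$labels)),
            file.path(out, "labels.csv"), sep = ",", row.names = FALSE,
            quote = FALSE)
write.table(data.frame(k = as.integer(names(model$silhouette_by_k)),
                       mean_silhouette = unname(model$silhouette_by_k)),
            file.path(out, "silhouette_by_k.csv"), sep = ",",
            row.names = FALSE, quote = FALSE)

cat(sprintf("silhouette selects k = %d (profile max %.3f)\n",
            model$selected_k, max(model$silhouette_by_k)))
for (cl in sort(unique(model$labels))) {
  members <- names(model$labels)[model$labels == cl]
  cat(sprintf("  cluster %d (n = %d): %s\n", cl, length(members),
              paste(members, collapse = ", ")))
}

ward <- suppressMessages(behavior_linkage(Dsum, method = "ward"))
ward_model <- select_k(ward, Dsum)
same <- all(table(model$labels, ward_model$labels) %in%
              c(0, table(model$labels)))
cat(sprintf("Ward check: k = %d, %s partition\n", ward_model$selected_k,
            if (same) "identical" else "different"))

resampled <- lapply(meta$trial_id, function(id) {
  read_skeleton_csv(file.path(tdir, paste0(id, "_object_resampled.csv")),
                    coordinate_frame = "object")
})
names(resampled) <- meta$trial_id
for (cl in sort(unique(model$labels))) {
  av <- average_behavior(resampled[names(model$labels)[model$labels == cl]],
                         cluster_id = cl)
  write_skeleton_csv(
    skeleton_sequence(sprintf("cluster%d_average", cl), av$frames, "object"),
    file.path(out, sprintf("cluster%d_average.csv", cl)))
}
cat("wrote linkage, labels, silhouette profile and cluster averages under",
    out, "\n")
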