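#!/usr/bin/env Rscript
# Stage 5: the 2-D behavior map.
#
# Metric MDS (stress majorization, best of 8 restarts) of Dsum, then the map
# colored three ways: by seat type (product), by Barthel Index and by MMSE.
# The question the colorings answer: does position on the map follow the
# seat's standing aid or the person's physical/cognitive ability?

library(stsmap)

out <- "results/analysis"
meta <- read_metadata_tsv(file.path(out, "metadata.tsv"))
Dsum <- read_matrix_csv(file.path(out, "Dsum.csv"))
labels <- read.csv(file.path(out, "labels.csv"))

emb <- mds_embed(Dsum, dim = 2, seed = 1, n_restarts = 8)
map <- annotate_map(emb, meta)
write.table(map, file.path(out, "map.csv"), sep = ",", row.names = FALSE,
            quote = FALSE)

cat(sprintf("embedding stress %.4g (best of %d restarts)\n",
            emb$stress, emb$n_restarts))
fwd <- c("no31_4", "no32_2")
E <- as.matrix(dist(emb$coordinates))
diag(E) <- Inf
cat(sprintf("nearest neighbor of %s on the map: %s\n", fwd,
            rownames(E)[apply(E[fwd, ], 1, which.min)]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  map$cluster <- factor(labels$cluster[match(map$trial_id, labels$trial_id)])
  fdir <- file.path(out, "figures")
  dir.create(fdir, showWarnings = FALSE)
  base <- ggplot(map, aes(x, y)) +
    geom_text(aes(label = trial_id), vjust = -0.8, size = 2.5) +
    coord_equal() + theme_minimal() +
    labs(x = "MDS dimension 1 (m)", y = "MDS dimension 2 (m)")
  ggsave(file.path(fdir, "map_product.png"),
         base + geom_point(aes(color = product, shape = cluster), size = 3),
         width = 7, height = 5, dpi = 150)
  ggsave(file.path(fdir, "map_BI.png"),
         base + geom_point(aes(color = BI, shape = cluster), size = 3),
         width = 7, height = 5, dpi = 150)
  ggsave(file.path(fdir, "map_MMSE.png"),
         base + geom_point(aes(color = MMSE, shape = cluster), size = 3),
         width = 7, height = 5, dpi = 150)
  cat("figures written under", fdir, "\n")
}
cat("wrote", file.path(out, "map.csv"), "\n")
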