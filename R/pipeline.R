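# End-to-end pipeline: simulate (or accept) a behavior library, estimate
# object frames, normalize and resample trajectories, compute dissimilarities,
# cluster with silhouette model selection, average each cluster's motion, and
# embed the library in a 2-D map annotated with seat type, BI and MMSE.

#' Pipeline configuration
#'
#' Collects the method constants. The defaults reproduce the reference
#' analysis: 500-frame resampling, Manhattan trajectory distance, UPGMA
#' linkage, silhouette scan over k = 2..12, 2-D metric MDS with 8 restarts.
#'
#' @param n_frames Resampled frame count.
#' @param distance_norm `"manhattan"` or `"euclidean_per_frame"`.
#' @param linkage_method `"upgma"` or `"ward"`.
#' @param k_min,k_max Silhouette scan range for the cluster count.
#' @param mds_dim,mds_restarts Embedding dimension and restart count.
#' @param noise_sd,separation,n_points Synthetic-library generator settings
#'   (see [simulate_library()]).
#' @param write_trials Whether [run_pipeline()] also writes per-trial
#'   skeletons and scans when given an output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_frames = 500L, distance_norm = "manhattan",
                            linkage_method = "upgma", k_min = 2L, k_max = 12L,
                            mds_dim = 2L, mds_restarts = 8L,
                            noise_sd = 0.01, separation = 1, n_points = 800L,
                            write_trials = TRUE) {
  cfg <- list(n_frames = as.integer(n_frames),
              distance_norm = match.arg(distance_norm,
                                        c("manhattan", "euclidean_per_frame")),
              linkage_method = match.arg(linkage_method, c("upgma", "ward")),
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              mds_dim = as.integer(mds_dim),
              mds_restarts = as.integer(mds_restarts),
              noise_sd = noise_sd, separation = separation,
              n_points = as.integer(n_points),
              write_trials = isTRUE(write_trials))
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2")
  if (cfg$k_min < 2L || cfg$k_max < cfg$k_min) stop("need 2 <= k_min <= k_max")
  structure(cfg, class = "pipeline_config")
}

#' Run the full behavior-analysis pipeline
#'
#' Simulates the 24-trial library under `seed` (unless an existing
#' `behavior_library` is passed), then runs every stage: per-trial object
#' frames from the seat scans, normalization into object coordinates,
#' resampling to the common clock, per-joint and summed distance matrices,
#' hierarchical clustering with silhouette-selected k, cluster-average
#' motions, metric MDS, and the annotated 2-D map. With `out_dir` set, every
#' intermediate artifact is written (metadata TSV, object-frame JSONs,
#' skeleton CSVs, distance CSVs, linkage CSV + Newick, labels and silhouette
#' profile, embedding and map CSVs, cluster averages, and a JSON manifest of
#' the configuration and seeds).
#'
#' A fixed seed makes the run deterministic end to end.
#'
#' @param seed Integer master seed.
#' @param config A [pipeline_config()].
#' @param library Optional pre-built `behavior_library`; by default one is
#'   simulated from `seed` and `config`.
#' @param out_dir Optional output directory.
#' @return A list (class `pipeline_result`) with `metadata`, `frames`
#'   (object frames), `normalized`, `resampled`, `distances`, `tree`,
#'   `model`, `averages`, `embedding`, `map`, `config`, `seed`.
#' @export
run_pipeline <- function(seed = 1L, config = pipeline_config(),
                         library = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(library)) {
    library <- simulate_library(seed, noise_sd = config$noise_sd,
                                separation = config$separation,
                                n_points = config$n_points)
  }
  stopifnot(inherits(library, "behavior_library"))
  n <- length(library$trials)
  if (config$k_max >= n) {
    stop(sprintf("k_max (%d) must be below the trial count (%d)",
                 config$k_max, n))
  }

  frames <- lapply(library$trials, function(tr) {
    object_frame_from_scan(tr$scan, skeleton_hint = tr$sequence)
  })
  normalized <- Map(function(tr, fr) normalize_sequence(tr$sequence, fr),
                    library$trials, frames)
  resampled <- lapply(normalized, resample_sequence, n_out = config$n_frames)
  distances <- distance_matrix(resampled, norm = config$distance_norm)
  tree <- behavior_linkage(distances, method = config$linkage_method)
  model <- select_k(tree, distances, k_range = config$k_min:config$k_max)
  averages <- lapply(sort(unique(model$labels)), function(cl) {
    average_behavior(resampled[model$labels == cl], cluster_id = cl)
  })
  embedding <- mds_embed(distances, dim = config$mds_dim, seed = seed,
                         n_restarts = config$mds_restarts)
  map <- annotate_map(embedding, library$metadata)

  result <- structure(list(
    metadata = library$metadata, library = library, frames = frames,
    normalized = normalized, resampled = resampled, distances = distances,
    tree = tree, model = model, averages = averages, embedding = embedding,
    map = map, config = config, seed = as.integer(seed)
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  sizes <- sort(table(x$model$labels), decreasing = TRUE)
  cat(sprintf("<pipeline_result> %d trials (seed %d): k = %d, cluster sizes %s, MDS stress %.4g\n",
              length(x$resampled), x$seed, x$model$selected_k,
              paste(sizes, collapse = "/"), x$embedding$stress))
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config

  write_metadata_tsv(result$metadata, file.path(out_dir, "metadata.tsv"))
  jsonlite::write_json(list(
    package = "stsmap",
    version = as.character(utils::packageVersion("stsmap")),
    seed = result$seed,
    config = unclass(cfg)
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  if (cfg$write_trials) {
    tdir <- file.path(out_dir, "trials")
    dir.create(tdir, showWarnings = FALSE)
    for (id in names(result$resampled)) {
      write_skeleton_csv(result$library$trials[[id]]$sequence,
                         file.path(tdir, paste0(id, "_camera.csv")))
      write_skeleton_csv(result$resampled[[id]],
                         file.path(tdir, paste0(id, "_object_resampled.csv")))
      write_seat_scan(result$library$trials[[id]]$scan, tdir, name = id)
      write_object_frame_json(result$frames[[id]],
                              file.path(tdir, paste0(id, "_frame.json")))
    }
  }

  write_matrix_csv(result$distances$total, file.path(out_dir, "Dsum.csv"))
  jdir <- file.path(out_dir, "per_joint")
  dir.create(jdir, showWarnings = FALSE)
  for (j in names(result$distances$per_joint)) {
    write_matrix_csv(result$distances$per_joint[[j]],
                     file.path(jdir, paste0("D_", j, ".csv")))
  }

  write_linkage_csv(result$tree, file.path(out_dir, "linkage.csv"))
  export_newick(result$tree, file.path(out_dir, "dendrogram.nwk"))

  labels_df <- data.frame(trial_id = names(result$model$labels),
                          cluster = unname(result$model$labels))
  utils::write.table(labels_df, file.path(out_dir, "labels.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  sil_df <- data.frame(k = as.integer(names(result$model$silhouette_by_k)),
                       mean_silhouette = unname(result$model$silhouette_by_k))
  utils::write.table(sil_df, file.path(out_dir, "silhouette_by_k.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)

  for (av in result$averages) {
    avseq <- skeleton_sequence(sprintf("cluster%d_average", av$cluster_id),
                               av$frames, "object")
    write_skeleton_csv(avseq, file.path(
      out_dir, sprintf("cluster%d_average.csv", av$cluster_id)))
  }

  emb_df <- data.frame(trial_id = rownames(result$embedding$coordinates),
                       result$embedding$coordinates, row.names = NULL)
  utils::write.table(emb_df, file.path(out_dir, "embedding.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$map, file.path(out_dir, "map.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
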