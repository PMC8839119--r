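# Hierarchical clustering of behaviors on the Dsum dissimilarity, silhouette
# selection of the cluster count, and cluster-average motions.

#' Hierarchical clustering of a behavior distance matrix
#'
#' Agglomerative clustering on the precomputed dissimilarities, with average
#' linkage (UPGMA, the default) or Ward linkage. UPGMA merges the pair of
#' clusters with the smallest mean cross-pair distance; on a metric input its
#' merge heights are non-decreasing. Ward formally assumes squared Euclidean
#' input; applying it to the Manhattan-sum matrix is a pragmatic check that
#' the partition is linkage-robust, and is reported with that caveat.
#'
#' @param D A `behavior_distance` or symmetric n x n matrix.
#' @param method `"upgma"` (average linkage) or `"ward"`.
#' @return An object of class `linkage_tree`: list with the `hclust` fit,
#'   `method`, `merges` (data.frame `child_a`, `child_b`, `height`, `size`;
#'   negative children are leaves) and `labels_` (trial ids).
#' @export
behavior_linkage <- function(D, method = c("upgma", "ward")) {
  method <- match.arg(method)
  M <- as_dist_matrix(D)
  if (nrow(M) < 2L) stop("need at least 2 trials to cluster")
  if (any(abs(diag(M)) > 1e-9)) stop("distance matrix must have a zero diagonal")
  if (method == "ward" && nrow(M) > 2L) {
    message("note: Ward linkage applied to non-Euclidean (Manhattan-sum) dissimilarities")
  }
  hc <- stats::hclust(stats::as.dist(M),
                      method = if (method == "upgma") "average" else "ward.D2")
  sizes <- integer(nrow(M) - 1L)
  count <- function(x) if (x < 0) 1L else sizes[x]
  for (i in seq_len(nrow(hc$merge))) {
    sizes[i] <- count(hc$merge[i, 1]) + count(hc$merge[i, 2])
  }
  merges <- data.frame(child_a = hc$merge[, 1], child_b = hc$merge[, 2],
                       height = hc$height, size = sizes)
  structure(list(hclust = hc, method = method, merges = merges,
                 labels_ = rownames(M)),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %s linkage, %d leaves, %d merges\n",
              x$method, length(x$labels_), nrow(x$merges)))
  invisible(x)
}

#' Mean silhouette coefficient of a clustering
#'
#' For each trial, `s_i = (b_i - a_i) / max(a_i, b_i)` where `a_i` is its
#' mean distance to the other members of its cluster and `b_i` the smallest
#' mean distance to any other cluster; members of singleton clusters
#' contribute `s_i = 0`. Returns the mean over trials, in `[-1, 1]`.
#'
#' @param D A `behavior_distance` or symmetric matrix.
#' @param labels Integer cluster assignment per trial, `2 <= k <= n - 1`
#'   distinct values, every cluster non-empty.
#' @return Mean silhouette width.
#' @export
silhouette_score <- function(D, labels) {
  M <- as_dist_matrix(D)
  n <- nrow(M)
  labels <- as.integer(factor(labels))
  if (length(labels) != n) stop("labels must have one entry per trial")
  k <- length(unique(labels))
  if (k < 2L) stop("silhouette is undefined for a single cluster")
  if (k >= n) stop("silhouette is degenerate when every trial is its own cluster")
  sil <- cluster::silhouette(labels, dmatrix = M)
  mean(sil[, "sil_width"])
}

#' Cut a linkage tree at each candidate k and select by silhouette
#'
#' Computes the mean silhouette of the partition obtained by cutting the
#' dendrogram at each `k` in `k_range` and selects the maximizer (ties go to
#' the smallest k, preferring the most parsimonious clustering). The full
#' silhouette-versus-k profile is retained for inspection.
#'
#' @param tree A `linkage_tree`.
#' @param D The `behavior_distance` (or matrix) the tree was built from.
#' @param k_range Candidate cluster counts, within `[2, n - 1]`; the default
#'   scans 2 up to `min(12, n - 1)`.
#' @return An object of class `cluster_model`: list with `selected_k`, `k`
#'   (same as `selected_k`), `labels` (named by trial), `silhouette_by_k`,
#'   `tree`.
#' @export
select_k <- function(tree, D, k_range = NULL) {
  stopifnot(inherits(tree, "linkage_tree"))
  M <- as_dist_matrix(D)
  n <- nrow(M)
  if (is.null(k_range)) k_range <- 2:min(12L, n - 1L)
  k_range <- as.integer(k_range)
  if (length(k_range) == 0L) stop("k_range is empty")
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    stop(sprintf("k_range must lie within [2, %d]", n - 1L))
  }
  sil <- vapply(k_range, function(k) {
    silhouette_score(M, stats::cutree(tree$hclust, k = k))
  }, numeric(1))
  names(sil) <- k_range
  selected <- k_range[which.max(sil)]
  labels <- stats::cutree(tree$hclust, k = selected)
  structure(list(selected_k = selected, k = selected, labels = labels,
                 silhouette_by_k = sil, tree = tree),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d (silhouette %.3f); sizes: %s\n",
              x$selected_k, max(x$silhouette_by_k),
              paste(sort(table(x$labels), decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Cluster-average behavior
#'
#' The elementwise arithmetic mean of the member trajectories on the common
#' 500-frame clock — the "representative motion" of a cluster. A
#' single-member cluster's average is that member.
#'
#' @param members Non-empty list of `resampled_sequence`s in the object frame
#'   with a common frame count.
#' @param cluster_id Optional identifier stored with the result.
#' @return An object of class `average_behavior`: list with `cluster_id`,
#'   `n`, `frames` (nframes x 13 x 3), `trial_ids`.
#' @export
average_behavior <- function(members, cluster_id = NA_integer_) {
  if (length(members) == 0L) stop("cannot average an empty cluster")
  dims <- unique(lapply(members, function(s) dim(s$frames)))
  if (length(dims) != 1L) stop("members must share one frame count")
  acc <- Reduce(`+`, lapply(members, function(s) s$frames))
  structure(list(
    cluster_id = cluster_id,
    n = length(members),
    frames = acc / length(members),
    trial_ids = vapply(members, function(s) s$trial_id, character(1))
  ), class = "average_behavior")
}
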