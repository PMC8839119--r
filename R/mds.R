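# Metric multidimensional scaling by majorization (SMACOF): place each
# behavior at a low-dimensional point z_i so that the Euclidean map distances
# reproduce the Dsum dissimilarities, minimizing the raw stress
# sum_{i<j} (d_ij - ||z_i - z_j||)^2.

# One majorization run from a given configuration; stress is non-increasing
# across iterations by construction (checked in tests).
smacof_run <- function(D, Z, max_iter = 2000L, tol = 1e-12) {
  n <- nrow(D)
  edist <- function(Z) as.matrix(stats::dist(Z))
  stress_of <- function(E) sum((D[upper.tri(D)] - E[upper.tri(E)])^2)

  E <- edist(Z)
  s <- stress_of(E)
  trace <- s
  for (it in seq_len(max_iter)) {
    # Guttman transform: Z <- (1/n) B(Z) Z with B_ij = -d_ij/e_ij (i != j,
    # e_ij > 0), diagonal minus the row sums.
    ratio <- ifelse(E > 0, D / E, 0)
    diag(ratio) <- 0
    B <- -ratio
    diag(B) <- rowSums(ratio)
    Z <- (B %*% Z) / n
    E <- edist(Z)
    s_new <- stress_of(E)
    trace <- c(trace, s_new)
    if (s - s_new < tol * max(s, .Machine$double.xmin)) {
      s <- s_new
      break
    }
    s <- s_new
  }
  list(Z = Z, stress = s, trace = trace)
}

# Gauge fixing: center, rotate onto principal axes, and fix each axis' sign
# by the coordinate of largest magnitude, so repeated runs are comparable.
align_configuration <- function(Z) {
  Z <- sweep(Z, 2, colMeans(Z))
  sv <- svd(Z)
  Z <- Z %*% sv$v
  for (k in seq_len(ncol(Z))) {
    i <- which.max(abs(Z[, k]))
    if (Z[i, k] < 0) Z[, k] <- -Z[, k]
  }
  Z
}

#' Embed behaviors in a low-dimensional map
#'
#' Metric MDS of the behavior dissimilarity matrix by iterative majorization
#' (SMACOF) of the raw stress `sum_{i<j} (d_ij - ||z_i - z_j||)^2`, taking
#' the best of `n_restarts` runs: one initialized from classical scaling and
#' the rest from seeded random configurations. The returned configuration is
#' centered at the origin and rotated onto its principal axes (with a
#' deterministic sign rule) so that runs are comparable despite the
#' rotation/reflection indeterminacy of MDS.
#'
#' @param D A `behavior_distance` or symmetric dissimilarity matrix, n >= 3.
#' @param dim Embedding dimension (default 2).
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of runs (>= 1); the minimum-stress run is kept.
#' @param max_iter,tol Majorization stopping rule: stop when the stress
#'   decrease falls below `tol` relative to the current stress.
#' @return An object of class `behavior_embedding`: list with `coordinates`
#'   (n x dim, rownames = trial ids), `stress` (the restart minimum),
#'   `stress_by_restart`, `stress_trace` (per-iteration stress of the best
#'   run), `seed`, `n_restarts`.
#' @export
mds_embed <- function(D, dim = 2L, seed = 1L, n_restarts = 8L,
                      max_iter = 2000L, tol = 1e-12) {
  M <- as_dist_matrix(D)
  n <- nrow(M)
  if (n < 3L) stop("embedding needs at least 3 trials")
  dim <- as.integer(dim)
  if (dim < 1L || dim >= n) stop("dim must be in [1, n - 1]")
  n_restarts <- max(1L, as.integer(n_restarts))

  inits <- vector("list", n_restarts)
  Z0 <- suppressWarnings(stats::cmdscale(M, k = dim))
  if (ncol(Z0) < dim) {
    Z0 <- cbind(Z0, matrix(0, n, dim - ncol(Z0)))
  }
  inits[[1]] <- Z0
  if (n_restarts > 1L) {
    scale0 <- max(M) / 2
    rand <- with_seed(seed, lapply(seq_len(n_restarts - 1L), function(i) {
      matrix(stats::rnorm(n * dim, sd = scale0), n, dim)
    }))
    inits[2:n_restarts] <- rand
  }
  runs <- lapply(inits, function(Z) smacof_run(M, Z, max_iter, tol))
  stresses <- vapply(runs, function(r) r$stress, numeric(1))
  best <- runs[[which.min(stresses)]]

  Z <- align_configuration(best$Z)
  rownames(Z) <- rownames(M)
  colnames(Z) <- paste0("dim", seq_len(dim))
  structure(list(coordinates = Z, stress = min(stresses),
                 stress_by_restart = stresses, stress_trace = best$trace,
                 seed = as.integer(seed), n_restarts = n_restarts),
            class = "behavior_embedding")
}

#' @export
print.behavior_embedding <- function(x, ...) {
  cat(sprintf("<behavior_embedding> %d x %d, stress %.4g (best of %d restarts)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress, x$n_restarts))
  invisible(x)
}

#' Join a 2-D behavior map with trial metadata
#'
#' Attaches seat type (product), Barthel Index and MMSE to each embedded
#' trial, producing the table behind the colored behavior maps.
#'
#' @param emb A `behavior_embedding` with 2-D coordinates and trial-id
#'   rownames.
#' @param metadata Data frame with columns `trial_id`, `product`, `BI`,
#'   `MMSE` covering every embedded trial.
#' @return Data frame with columns `trial_id`, `x`, `y`, `product`, `BI`,
#'   `MMSE`, one row per embedded trial in embedding order.
#' @export
annotate_map <- function(emb, metadata) {
  stopifnot(inherits(emb, "behavior_embedding"))
  if (ncol(emb$coordinates) < 2L) stop("map annotation needs a 2-D embedding")
  ids <- rownames(emb$coordinates)
  if (is.null(ids)) stop("embedding has no trial ids")
  need <- c("trial_id", "product", "BI", "MMSE")
  if (!all(need %in% names(metadata))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(ids, metadata$trial_id)
  if (length(missing) > 0L) {
    stop("metadata rows missing for trials: ", paste(missing, collapse = ", "))
  }
  idx <- match(ids, metadata$trial_id)
  data.frame(
    trial_id = ids,
    x = emb$coordinates[, 1],
    y = emb$coordinates[, 2],
    product = metadata$product[idx],
    BI = metadata$BI[idx],
    MMSE = metadata$MMSE[idx],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
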