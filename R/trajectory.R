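# Time normalization and trajectory dissimilarity: every behavior is
# resampled to a common 500-frame clock by natural cubic splines, and pairs
# of behaviors are compared by the Manhattan distance between their joint
# trajectories, summed over the 13 joints.

#' Resample a skeleton sequence to a fixed frame count
#'
#' Interpolates each of the 39 coordinate channels with a natural cubic
#' spline over normalized time and evaluates it at `n_out` equispaced points,
#' so behaviors of different durations share a common 500-frame clock. Time
#' is parameterized by frame index, `u = (frame - 1) / (T - 1)`, unless the
#' sequence carries timestamps, in which case those are normalized to
#' `[0, 1]` instead. The first and last output frames equal the input
#' endpoints.
#'
#' @param seq A `skeleton_sequence` (typically object-frame), `T >= 4`.
#' @param n_out Output frame count (default 500).
#' @return A `skeleton_sequence` with `n_out` frames and class
#'   `resampled_sequence` prepended.
#' @export
resample_sequence <- function(seq, n_out = 500L) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  T_ <- dim(seq$frames)[1]
  if (T_ < 4L) stop("resampling needs at least 4 frames (cubic spline knots)")
  if (!all(is.finite(seq$frames))) stop("sequence contains non-finite coordinates")
  n_out <- as.integer(n_out)
  if (n_out < 2L) stop("n_out must be >= 2")

  u_in <- if (!is.null(seq$time)) {
    tt <- as.double(seq$time)
    if (any(diff(tt) <= 0)) stop("timestamps must be strictly increasing")
    (tt - tt[1]) / (tt[T_] - tt[1])
  } else {
    (seq_len(T_) - 1) / (T_ - 1)
  }
  u_out <- seq(0, 1, length.out = n_out)

  out <- array(0, dim = c(n_out, 13, 3))
  for (j in 1:13) {
    for (k in 1:3) {
      out[, j, k] <- stats::spline(u_in, seq$frames[, j, k], xout = u_out,
                                   method = "natural")$y
    }
  }
  # pin endpoints to the data exactly (spline evaluates them exactly up to
  # rounding; make the contract literal)
  out[1, , ] <- seq$frames[1, , ]
  out[n_out, , ] <- seq$frames[T_, , ]

  res <- skeleton_sequence(seq$trial_id, out, seq$coordinate_frame,
                           truth = seq$truth)
  class(res) <- c("resampled_sequence", class(res))
  res
}

#' Trajectory distance for one joint
#'
#' The dissimilarity of one joint's trajectory between two behaviors on the
#' common clock: the sum over frames of the Manhattan (L1) norm of the
#' coordinate difference, `sum_t |dx| + |dy| + |dz|` (meters). A
#' Euclidean-per-frame variant is available for sensitivity checks.
#'
#' @param A,B `resampled_sequence`s with equal frame counts.
#' @param joint Joint name (see [joint_names()]) or index 1-13.
#' @param norm `"manhattan"` (default) or `"euclidean_per_frame"`.
#' @return Distance in meters.
#' @export
joint_distance <- function(A, B, joint, norm = c("manhattan", "euclidean_per_frame")) {
  norm <- match.arg(norm)
  stopifnot(inherits(A, "skeleton_sequence"), inherits(B, "skeleton_sequence"))
  if (dim(A$frames)[1] != dim(B$frames)[1]) {
    stop("sequences have different frame counts; resample first")
  }
  j <- if (is.character(joint)) match(joint, STS_JOINTS) else as.integer(joint)
  if (is.na(j) || j < 1L || j > 13L) stop("unknown joint: ", joint)
  dif <- A$frames[, j, ] - B$frames[, j, ]
  if (norm == "manhattan") sum(abs(dif)) else sum(sqrt(rowSums(dif^2)))
}

#' Behavior dissimilarity matrices
#'
#' Computes, for a library of resampled behaviors, the 13 per-joint distance
#' matrices `Dj` (each entry the [joint_distance()] of a trial pair) and
#' their sum `Dsum`, the overall behavior dissimilarity used for clustering
#' and mapping. Each per-joint matrix is a Manhattan distance over the
#' flattened 500 x 3 trajectory, so `Dsum` is a metric.
#'
#' @param library List of `resampled_sequence`s with unique trial ids and a
#'   common frame count; length >= 2.
#' @param norm Passed to [joint_distance()].
#' @return An object of class `behavior_distance`: list with `trial_ids`,
#'   `per_joint` (named list of 13 n x n matrices) and `total` (`Dsum`).
#' @export
distance_matrix <- function(library, norm = c("manhattan", "euclidean_per_frame")) {
  norm <- match.arg(norm)
  n <- length(library)
  if (n < 2L) stop("need at least 2 trials")
  ids <- unname(vapply(library, function(s) s$trial_id, character(1)))
  if (anyDuplicated(ids)) stop("duplicate trial_ids: ", ids[duplicated(ids)][1])
  n_frames <- unique(vapply(library, function(s) dim(s$frames)[1], integer(1)))
  if (length(n_frames) != 1L) stop("all trials must share one frame count")

  per_joint <- vector("list", 13L)
  names(per_joint) <- STS_JOINTS
  for (j in 1:13) {
    M <- t(vapply(library, function(s) as.vector(s$frames[, j, ]),
                  numeric(n_frames * 3L)))
    Dj <- if (norm == "manhattan") {
      as.matrix(stats::dist(M, method = "manhattan"))
    } else {
      D <- matrix(0, n, n)
      for (a in seq_len(n - 1)) {
        for (b in (a + 1):n) {
          dif <- library[[a]]$frames[, j, ] - library[[b]]$frames[, j, ]
          D[a, b] <- D[b, a] <- sum(sqrt(rowSums(dif^2)))
        }
      }
      D
    }
    dimnames(Dj) <- list(ids, ids)
    per_joint[[j]] <- Dj
  }
  total <- Reduce(`+`, per_joint)
  structure(list(trial_ids = ids, per_joint = per_joint, total = total),
            class = "behavior_distance")
}

#' @export
print.behavior_distance <- function(x, ...) {
  cat(sprintf("<behavior_distance> %d trials; Dsum in [%.3g, %.3g] m\n",
              length(x$trial_ids), min(x$total), max(x$total[x$total > 0])))
  invisible(x)
}

# Accept either a behavior_distance or a plain symmetric matrix.
as_dist_matrix <- function(D) {
  if (inherits(D, "behavior_distance")) return(D$total)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  D
}
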