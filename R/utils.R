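# Internal helpers shared across modules. Units are meters everywhere.

# Canonical 13-joint set, in canonical order. All skeleton containers and
# files must use exactly these names in exactly this order.
STS_JOINTS <- c(
  "left_shoulder", "left_elbow", "left_wrist",
  "right_shoulder", "right_elbow", "right_wrist",
  "center_pelvis", "left_pelvis", "left_knee", "left_ankle",
  "right_pelvis", "right_knee", "right_ankle"
)

#' Canonical joint names
#'
#' The ordered set of 13 body joints used throughout the pipeline: shoulders,
#' elbows and wrists (left then right), the pelvis center, and left/right
#' pelvis, knee and ankle.
#'
#' @return Character vector of length 13.
#' @export
joint_names <- function() STS_JOINTS

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` sub-seeds from a master seed, each below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

unitize <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("cannot normalize a near-zero vector")
  v / nv
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(R %*% t(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

as_matrix3 <- function(x, what = "points") {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns (x, y, z)", what))
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop(sprintf("%s contain non-finite coordinates", what))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
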