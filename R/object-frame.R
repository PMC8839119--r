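# The object-centered coordinate system: a seat-anchored frame with origin at
# the armrest/handrail base, z along the seat-surface normal, x front-back
# and y left-right, built from least-squares plane fits of the seat surface
# and the backrest (chair/sofa) or side frame (bed). Re-expressing skeleton
# trajectories in this frame makes behaviors comparable across seats and
# camera placements.

#' Least-squares plane fit with the c = 1 parameterization
#'
#' Fits `a*X + b*Y + c*Z + d = 0` with `c` fixed to 1, i.e. solves
#' `[X Y 1] [a b d]' = -Z` in the least-squares sense via the closed form
#' `[a b d]' = -(P'^T P')^{-1} P'^T Z` (computed by QR for stability). This
#' parameterization assumes the plane is not vertical in camera coordinates
#' (a seat surface seen from a ceiling camera); near-vertical planes are
#' rejected because `c = 1` cannot represent them.
#'
#' @param points N x 3 matrix of coordinates (m), N >= 3, not collinear.
#' @return An object of class `plane_fit` with fields `a`, `b`, `c` (always
#'   1), `d`, `normal` (the unnormalized `[a, b, 1]`), and `rms_residual`,
#'   the root-mean-square of `a*X + b*Y + Z + d` over the input points (m).
#' @export
fit_seat_plane <- function(points) {
  P <- as_matrix3(points, "plane points")
  n <- nrow(P)
  if (n < 3L) stop("plane fit needs at least 3 points")

  A <- cbind(P[, 1], P[, 2], 1)
  qrA <- qr(A)
  if (qrA$rank < 3L) {
    stop("rank-deficient input: points are collinear, plane fit is undefined")
  }
  # Orientation guard via the total-least-squares normal (smallest principal
  # direction of the centered cloud): |normal_z| < 0.1 means the plane is
  # nearly vertical and the z = f(x, y) parameterization degenerates.
  ctr <- sweep(P, 2, colMeans(P))
  tls_normal <- svd(ctr, nu = 0)$v[, 3]
  if (abs(tls_normal[3]) < 0.1) {
    stop("near-vertical plane: the c = 1 parameterization cannot represent it")
  }

  coef <- qr.coef(qrA, -P[, 3])
  a <- coef[1]; b <- coef[2]; d <- coef[3]
  res <- A %*% coef + P[, 3]
  structure(list(
    a = unname(a), b = unname(b), c = 1, d = unname(d),
    normal = c(unname(a), unname(b), 1),
    rms_residual = sqrt(mean(res^2)),
    n_points = n
  ), class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("<plane_fit> %.6g x + %.6g y + z + %.6g = 0 (rms %.3g m, n = %d)\n",
              x$a, x$b, x$d, x$rms_residual, x$n_points))
  invisible(x)
}

#' Build the object-centered orthonormal basis
#'
#' Constructs the seat-anchored basis from two plane fits: `ez` is the unit
#' normal of the seat surface ("up"), `ex_raw` the unit normal of the
#' backrest/side frame (roughly front-back but not orthogonal to `ez`),
#' `ey = ez x ex_raw` normalized ("left-right"), and the true front-back
#' axis re-orthogonalized as `ex = ey x ez`.
#'
#' The plane normals carry an orientation ambiguity (the `c = 1` fit always
#' reports a normal with positive camera-z). When `skeleton_hint` is
#' supplied, signs are disambiguated from the data: `ez` is flipped so the
#' trial-mean shoulder position lies on the positive side of the seat plane
#' (up = seat toward shoulders), and `ex` is flipped (with `ey` flipped
#' along with it, preserving right-handedness) so the pelvis center's net
#' first-to-last displacement has non-negative `ex` component (forward =
#' direction of standing travel). Without a hint the raw orientations are
#' kept.
#'
#' @param seat_fit [fit_seat_plane()] of the seat surface.
#' @param reference_fit [fit_seat_plane()] of the backrest or side frame.
#' @param skeleton_hint Optional camera-frame `skeleton_sequence` used for
#'   sign disambiguation.
#' @return List with unit vectors `ex`, `ey`, `ez` and the pre-orthogonalized
#'   `ex_raw`.
#' @export
build_basis <- function(seat_fit, reference_fit, skeleton_hint = NULL) {
  stopifnot(inherits(seat_fit, "plane_fit"), inherits(reference_fit, "plane_fit"))
  ez <- unitize(seat_fit$normal)
  ex_raw <- unitize(reference_fit$normal)
  cr <- cross3(ez, ex_raw)
  if (sqrt(sum(cr^2)) < 1e-8) {
    stop("backrest plane parallel to seat plane: basis is undefined")
  }

  if (!is.null(skeleton_hint)) {
    stopifnot(inherits(skeleton_hint, "skeleton_sequence"))
    fr <- skeleton_hint$frames
    shoulders <- rbind(fr[, "left_shoulder", ], fr[, "right_shoulder", ])
    # signed offset from the seat plane along its normal direction
    side <- mean(seat_fit$a * shoulders[, 1] + seat_fit$b * shoulders[, 2] +
                   shoulders[, 3] + seat_fit$d)
    if (side < 0) ez <- -ez
  }
  ey <- unitize(cross3(ez, ex_raw))
  ex <- cross3(ey, ez)
  if (!is.null(skeleton_hint)) {
    fr <- skeleton_hint$frames
    travel <- fr[dim(fr)[1], "center_pelvis", ] - fr[1, "center_pelvis", ]
    if (sum(travel * ex) < 0) {
      ex <- -ex
      ey <- -ey
    }
  }
  list(ex = ex, ey = ey, ez = ez, ex_raw = ex_raw)
}

#' Assemble the camera-to-object rigid transform
#'
#' Stacks the basis into the rotation `R` (rows `ex`, `ey`, `ez`) and builds
#' the homogeneous transform `H = [R, -R %*% P0; 0 0 0 1]` mapping a
#' camera-frame point `p` to object coordinates `R %*% (p - P0)`. The anchor
#' `P0` (armrest/handrail base) therefore maps to the origin.
#'
#' @param basis List with orthonormal unit vectors `ex`, `ey`, `ez` (e.g.
#'   from [build_basis()]).
#' @param origin `P0`, 3-vector in camera coordinates (m).
#' @return An object of class `object_frame` with fields `ex`, `ey`, `ez`,
#'   `ex_raw` (if present in `basis`), `R`, `P0`, `H`.
#' @export
make_transform <- function(basis, origin) {
  R <- rbind(ex = basis$ex, ey = basis$ey, ez = basis$ez)
  colnames(R) <- c("x", "y", "z")
  if (!is_rotation(R)) {
    stop("basis is not orthonormal and right-handed")
  }
  if (length(origin) != 3L || !all(is.finite(origin))) {
    stop("origin P0 must be a finite 3-vector")
  }
  P0 <- as.double(origin)
  H <- rbind(cbind(R, -R %*% P0), c(0, 0, 0, 1))
  dimnames(H) <- NULL
  structure(list(ex = basis$ex, ey = basis$ey, ez = basis$ez,
                 ex_raw = basis$ex_raw, R = unname(R), P0 = P0, H = H),
            class = "object_frame")
}

#' @export
print.object_frame <- function(x, ...) {
  cat("<object_frame> P0 =", sprintf("%.4f", x$P0), "\n")
  cat("  ex =", sprintf("%+.4f", x$ex), "\n")
  cat("  ey =", sprintf("%+.4f", x$ey), "\n")
  cat("  ez =", sprintf("%+.4f", x$ez), "\n")
  invisible(x)
}

#' Transform camera-frame points to object coordinates
#'
#' @param frame An `object_frame`.
#' @param points N x 3 matrix in camera coordinates (m).
#' @return N x 3 matrix in object coordinates.
#' @export
transform_points <- function(frame, points) {
  stopifnot(inherits(frame, "object_frame"))
  P <- as_matrix3(points)
  t(frame$R %*% (t(P) - frame$P0))
}

#' Estimate the object frame of a seat scan
#'
#' Convenience wrapper: fits the seat-surface and reference patches, builds
#' the sign-disambiguated basis, and anchors the transform at the annotated
#' armrest/handrail base point.
#'
#' @param scan A `seat_scan`.
#' @param skeleton_hint Optional camera-frame `skeleton_sequence` for sign
#'   disambiguation (see [build_basis()]).
#' @return An `object_frame`.
#' @export
object_frame_from_scan <- function(scan, skeleton_hint = NULL) {
  stopifnot(inherits(scan, "seat_scan"))
  seat_fit <- fit_seat_plane(scan$surface_points)
  ref_fit <- fit_seat_plane(scan$reference_points)
  basis <- build_basis(seat_fit, ref_fit, skeleton_hint)
  fr <- make_transform(basis, scan$anchor_point)
  fr$seat_fit <- seat_fit
  fr$reference_fit <- ref_fit
  fr
}

#' Re-express a skeleton sequence in object coordinates
#'
#' Applies the camera-to-object transform to every joint in every frame.
#'
#' @param seq A camera-frame `skeleton_sequence`.
#' @param frame An `object_frame` for the seat the behavior used.
#' @return The sequence with `coordinate_frame = "object"`.
#' @export
normalize_sequence <- function(seq, frame) {
  stopifnot(inherits(seq, "skeleton_sequence"), inherits(frame, "object_frame"))
  if (seq$coordinate_frame != "camera") {
    stop("sequence is already in object coordinates")
  }
  out <- seq
  for (t in seq_len(dim(seq$frames)[1])) {
    out$frames[t, , ] <- transform_points(frame, seq$frames[t, , ])
  }
  out$coordinate_frame <- "object"
  out$object_frame <- frame
  out
}
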