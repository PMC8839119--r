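# Synthetic seat scans: planar seat-surface and backrest/side-frame patches
# rendered in an arbitrary camera frame, with the armrest/handrail base point
# annotated, emulating patches segmented from ceiling-camera depth data.

# Seat geometry is authored in a "canonical" seat frame: floor at z = 0,
# z up, x front-back (+x toward the sitter's front), y left-right, the
# seat-surface center at (0, 0, seat_height). The backrest stands behind the
# seat (x = -seat_depth/2 at seat level), tilted backward from vertical by
# `backrest_tilt` so that its plane is representable in the z = f(x, y)
# parameterization the plane fit uses.

canonical_anchor <- function(spec) {
  c(0, 0, spec$seat_height) + spec$anchor_offset
}

canonical_surface_points <- function(spec, n) {
  x <- stats::runif(n, -spec$seat_depth / 2, spec$seat_depth / 2)
  y <- stats::runif(n, -spec$seat_width / 2, spec$seat_width / 2)
  cbind(x = x, y = y, z = rep(spec$seat_height, n))
}

canonical_reference_points <- function(spec, n, extent = 0.4) {
  # Backrest (chair/sofa) or side frame (bed): plane through the seat's rear
  # edge, leaning back by backrest_tilt; in-plane "up" direction is
  # (-sin(tilt), 0, cos(tilt)).
  y <- stats::runif(n, -spec$seat_width / 2, spec$seat_width / 2)
  s <- stats::runif(n, 0, extent)
  base <- c(-spec$seat_depth / 2, 0, spec$seat_height)
  up <- c(-sin(spec$backrest_tilt), 0, cos(spec$backrest_tilt))
  cbind(x = base[1] + s * up[1], y = y, z = base[3] + s * up[3])
}

apply_pose <- function(pose, pts) {
  t(pose$rotation %*% t(as_matrix3(pts)) + pose$translation)
}

#' Generate a synthetic seat scan
#'
#' Renders the seat-surface patch, the backrest/side-frame patch, and the
#' armrest/handrail base point of a seat in camera coordinates: canonical
#' geometry is moved rigidly by `pose`, then each measured point is perturbed
#' by isotropic Gaussian noise of standard deviation `noise_sd`. The anchor
#' point is an annotation, not a depth measurement, and is therefore stored
#' noise-free.
#'
#' The ground-truth object frame implied by the pose is retained in
#' `$truth` so downstream estimates can be checked against it.
#'
#' @param spec A [seat_spec()].
#' @param pose A [camera_pose()].
#' @param noise_sd Measurement noise standard deviation (m), >= 0.
#' @param n_points Points per patch (>= 10).
#' @param seed Integer seed.
#' @return An object of class `seat_scan` with fields `surface_points`
#'   (N x 3), `reference_points` (M x 3), `anchor_point` (3-vector),
#'   `seat_type`, and `truth` (list: `frame`, the ground-truth
#'   [make_transform()] result; `normal_camera`, the true seat-surface normal
#'   in camera coordinates; `pose`; `spec`).
#' @export
generate_seat_scan <- function(spec, pose, noise_sd = 0.005, n_points = 800L,
                               seed = 1L) {
  stopifnot(inherits(spec, "seat_spec"))
  if (!inherits(pose, "camera_pose")) {
    stop("pose must be a camera_pose (degenerate or missing rotation rejected)")
  }
  if (n_points < 10L) stop("n_points must be >= 10 per patch")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  with_seed(seed, {
    surf <- canonical_surface_points(spec, n_points)
    ref <- canonical_reference_points(spec, n_points)
    anchor_can <- canonical_anchor(spec)

    surf_cam <- apply_pose(pose, surf)
    ref_cam <- apply_pose(pose, ref)
    anchor_cam <- drop(pose$rotation %*% anchor_can + pose$translation)
    if (noise_sd > 0) {
      surf_cam <- surf_cam + matrix(stats::rnorm(length(surf_cam), sd = noise_sd),
                                    ncol = 3)
      ref_cam <- ref_cam + matrix(stats::rnorm(length(ref_cam), sd = noise_sd),
                                  ncol = 3)
    }
    Q <- pose$rotation
    truth_frame <- make_transform(
      list(ex = Q[, 1], ey = Q[, 2], ez = Q[, 3]), anchor_cam
    )
    structure(list(
      surface_points = surf_cam,
      reference_points = ref_cam,
      anchor_point = anchor_cam,
      seat_type = spec$seat_type,
      truth = list(frame = truth_frame, normal_camera = Q[, 3],
                   pose = pose, spec = spec)
    ), class = "seat_scan")
  })
}
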