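# Synthetic sit-to-stand skeleton sequences: three key poses (seated,
# transition, standing) per joint, interpolated smoothly in time, jittered,
# and rendered into an arbitrary camera frame.

#' Construct a skeleton sequence
#'
#' @param trial_id Trial identifier.
#' @param frames T x 13 x 3 array of joint coordinates (m); the joint
#'   dimension must follow [joint_names()] order.
#' @param coordinate_frame `"camera"` or `"object"`.
#' @param time Optional numeric vector of length T of timestamps (s).
#' @param truth Optional list of generator ground truth (synthetic data only).
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(trial_id, frames, coordinate_frame = c("camera", "object"),
                              time = NULL, truth = NULL) {
  coordinate_frame <- match.arg(coordinate_frame)
  frames <- validate_frames(frames)
  if (!is.null(time) && length(time) != dim(frames)[1]) {
    stop("time must have one entry per frame")
  }
  structure(list(
    trial_id = as.character(trial_id),
    joint_names = STS_JOINTS,
    frames = frames,
    frame_index = seq_len(dim(frames)[1]),
    coordinate_frame = coordinate_frame,
    time = time,
    truth = truth
  ), class = "skeleton_sequence")
}

validate_frames <- function(frames) {
  if (length(dim(frames)) != 3L || dim(frames)[2] != 13L || dim(frames)[3] != 3L) {
    stop("frames must be a T x 13 x 3 array")
  }
  if (dim(frames)[1] < 2L) stop("a skeleton sequence needs at least 2 frames")
  if (!all(is.finite(frames))) stop("frames contain non-finite coordinates")
  dimnames(frames) <- list(NULL, STS_JOINTS, c("x", "y", "z"))
  frames
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence> %s: %d frames x 13 joints, %s frame\n",
              x$trial_id, dim(x$frames)[1], x$coordinate_frame))
  invisible(x)
}

# One key pose: a 13 x 3 matrix in the canonical seat frame.
# `yh` is the hip-center y position; the armrest/handrail is on the +y side.
key_pose_seated <- function(h, yh) {
  shw <- 0.18; hipw <- 0.12
  rbind(
    left_shoulder  = c(-0.10, yh + shw, h + 0.55),
    left_elbow     = c(-0.02, yh + shw + 0.04, h + 0.30),
    left_wrist     = c(0.15, yh + 0.14, h + 0.12),
    right_shoulder = c(-0.10, yh - shw, h + 0.55),
    right_elbow    = c(-0.02, yh - shw - 0.04, h + 0.30),
    right_wrist    = c(0.15, yh - 0.14, h + 0.12),
    center_pelvis  = c(-0.10, yh, h + 0.05),
    left_pelvis    = c(-0.10, yh + hipw, h + 0.05),
    left_knee      = c(0.28, yh + hipw, h + 0.02),
    left_ankle     = c(0.33, yh + hipw, 0.08),
    right_pelvis   = c(-0.10, yh - hipw, h + 0.05),
    right_knee     = c(0.28, yh - hipw, h + 0.02),
    right_ankle    = c(0.33, yh - hipw, 0.08)
  )
}

key_pose_transition <- function(h, yh, arch, anchor) {
  shw <- 0.18; hipw <- 0.12; trunk <- 0.50
  pelvis_z <- h + 0.15
  sh_x <- -0.10 + arch$shoulder_forward_excursion
  sh_z <- pelvis_z + trunk * cos(arch$trunk_pitch_peak)
  lknee <- c(0.28, yh + hipw, h + 0.02)
  rknee <- c(0.28, yh - hipw, h + 0.02)
  if (arch$hand_target == "armrest_anchor") {
    # hand reaches the standing aid near its base; other hand pushes on the seat
    lwrist <- anchor + c(0.02, -0.02, 0.02)
    rwrist <- c(0.10, yh - 0.15, h + 0.05)
  } else {
    lwrist <- lknee + c(0.04, 0, 0.06)
    rwrist <- rknee + c(0.04, 0, 0.06)
  }
  lsh <- c(sh_x, yh + shw, sh_z)
  rsh <- c(sh_x, yh - shw, sh_z)
  rbind(
    left_shoulder  = lsh,
    left_elbow     = (lsh + lwrist) / 2 + c(0, 0.03, 0.02),
    left_wrist     = lwrist,
    right_shoulder = rsh,
    right_elbow    = (rsh + rwrist) / 2 + c(0, -0.03, 0.02),
    right_wrist    = rwrist,
    center_pelvis  = c(0.00, yh, pelvis_z),
    left_pelvis    = c(0.00, yh + hipw, pelvis_z),
    left_knee      = lknee,
    left_ankle     = c(0.33, yh + hipw, 0.08),
    right_pelvis   = c(0.00, yh - hipw, pelvis_z),
    right_knee     = rknee,
    right_ankle    = c(0.33, yh - hipw, 0.08)
  )
}

key_pose_standing <- function(yh) {
  shw <- 0.18; hipw <- 0.12
  rbind(
    left_shoulder  = c(0.10, yh + shw, 1.46),
    left_elbow     = c(0.10, yh + shw + 0.03, 1.16),
    left_wrist     = c(0.12, yh + shw + 0.03, 0.92),
    right_shoulder = c(0.10, yh - shw, 1.46),
    right_elbow    = c(0.10, yh - shw - 0.03, 1.16),
    right_wrist    = c(0.12, yh - shw - 0.03, 0.92),
    center_pelvis  = c(0.15, yh, 0.95),
    left_pelvis    = c(0.15, yh + hipw, 0.95),
    left_knee      = c(0.18, yh + hipw, 0.48),
    left_ankle     = c(0.20, yh + hipw, 0.08),
    right_pelvis   = c(0.15, yh - hipw, 0.95),
    right_knee     = c(0.18, yh - hipw, 0.48),
    right_ankle    = c(0.20, yh - hipw, 0.08)
  )
}

#' Generate a synthetic standing behavior
#'
#' Builds a sit-to-stand skeleton sequence from three key poses (seated,
#' transition, standing) interpolated per joint coordinate by a natural cubic
#' spline over normalized time, adds isotropic Gaussian jitter, and renders
#' the result into camera coordinates under `pose`. The jitter is drawn in the
#' canonical seat frame, so the same `archetype_spec` (including its seed)
#' rendered under two different camera poses describes the *same* noisy
#' behavior, moved rigidly — the property the object-centered normalization
#' is meant to exploit.
#'
#' The returned sequence keeps the generator's ground truth in `$truth`:
#' the object-frame trajectory (canonical coordinates re-expressed about the
#' armrest/handrail base) and the archetype label.
#'
#' @param arch An [archetype_spec()].
#' @param seat A [seat_spec()].
#' @param pose A [camera_pose()].
#' @param trial_id Trial identifier stored in the sequence.
#' @return A `skeleton_sequence` in the camera frame.
#' @export
generate_standing_behavior <- function(arch, seat, pose, trial_id = "synthetic") {
  if (!inherits(arch, "archetype_spec")) stop("unknown archetype specification")
  stopifnot(inherits(seat, "seat_spec"), inherits(pose, "camera_pose"))

  h <- seat$seat_height
  anchor <- canonical_anchor(seat)
  # Hip center sits `anchor_gap` from the standing aid along the width,
  # clamped so the sitter stays on the seat.
  yh <- anchor[2] - min(arch$anchor_gap, seat$seat_width - 0.10)

  keys <- array(0, dim = c(3, 13, 3))
  keys[1, , ] <- key_pose_seated(h, yh)
  keys[2, , ] <- key_pose_transition(h, yh, arch, anchor)
  keys[3, , ] <- key_pose_standing(yh)

  T_ <- arch$duration_frames
  u_key <- c(0, 0.45, 1)
  u <- seq(0, 1, length.out = T_)
  frames_can <- array(0, dim = c(T_, 13, 3))
  for (j in 1:13) {
    for (k in 1:3) {
      frames_can[, j, k] <- stats::spline(u_key, keys[, j, k], xout = u,
                                          method = "natural")$y
    }
  }
  frames_can <- with_seed(arch$seed, {
    if (arch$noise_sd > 0) {
      frames_can + array(stats::rnorm(length(frames_can), sd = arch$noise_sd),
                         dim = dim(frames_can))
    } else frames_can
  })

  truth_obj <- sweep(frames_can, 3, anchor, "-")
  dimnames(truth_obj) <- list(NULL, STS_JOINTS, c("x", "y", "z"))
  frames_cam <- array(0, dim = dim(frames_can))
  for (t in seq_len(T_)) {
    frames_cam[t, , ] <- apply_pose(pose, frames_can[t, , ])
  }
  skeleton_sequence(
    trial_id, frames_cam, "camera",
    truth = list(object_frames = truth_obj, archetype = arch$archetype,
                 arch = arch, seat = seat, pose = pose)
  )
}
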