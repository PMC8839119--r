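# Specifications for the synthetic-data generator: seat geometry, camera
# placement, and standing-behavior archetypes.

#' Seat geometry specification
#'
#' Describes one of the three seat classes observed in living spaces — a chair
#' with an armrest, a sofa with an armrest, or a nursing bed with a handrail —
#' as a small set of dimensions in meters. The armrest (or handrail) base is
#' the anchor of the object-centered coordinate system; `anchor_offset` places
#' it relative to the seat-surface center.
#'
#' Defaults are typical furniture dimensions; the seat classes differ mainly
#' in seat width (sofa and bed much wider than chair), which is what drives
#' where a person can sit relative to the standing aid.
#'
#' @param seat_type One of `"chair"`, `"sofa"`, `"nursing_bed"`.
#' @param seat_height Seat-surface height above the floor (m).
#' @param seat_depth Front-to-back extent of the seat surface (m).
#' @param seat_width Left-to-right extent of the seat surface (m).
#' @param armrest_height Armrest/handrail top height above the seat surface (m).
#' @param backrest_tilt Backrest (or bed side-frame) tilt from vertical (rad).
#' @param anchor_offset 3-vector (m): armrest/handrail base relative to the
#'   seat-surface center. Default puts it at seat level on the left edge.
#' @return An object of class `seat_spec`.
#' @export
seat_spec <- function(seat_type = c("chair", "sofa", "nursing_bed"),
                      seat_height = NULL, seat_depth = NULL, seat_width = NULL,
                      armrest_height = NULL, backrest_tilt = 20 * pi / 180,
                      anchor_offset = NULL) {
  seat_type <- match.arg(seat_type)
  def <- switch(seat_type,
    chair       = list(h = 0.42, d = 0.45, w = 0.52, a = 0.20),
    sofa        = list(h = 0.40, d = 0.58, w = 1.60, a = 0.20),
    nursing_bed = list(h = 0.45, d = 0.90, w = 1.90, a = 0.35)
  )
  spec <- list(
    seat_type = seat_type,
    seat_height = seat_height %||% def$h,
    seat_depth = seat_depth %||% def$d,
    seat_width = seat_width %||% def$w,
    armrest_height = armrest_height %||% def$a,
    backrest_tilt = backrest_tilt
  )
  spec$anchor_offset <- anchor_offset %||% c(0, spec$seat_width / 2, 0)
  lens <- unlist(spec[c("seat_height", "seat_depth", "seat_width", "armrest_height")])
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all seat dimensions must be positive finite lengths (m)")
  }
  if (length(spec$anchor_offset) != 3L || !all(is.finite(spec$anchor_offset))) {
    stop("anchor_offset must be a finite 3-vector (m)")
  }
  structure(spec, class = "seat_spec")
}

#' Camera pose (rigid transform from seat-canonical to camera coordinates)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation 3-vector (m).
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!is_rotation(rotation)) {
    stop("camera_pose rotation must be orthonormal with determinant +1")
  }
  if (length(translation) != 3L || !all(is.finite(translation))) {
    stop("camera_pose translation must be a finite 3-vector (m)")
  }
  structure(list(rotation = rotation, translation = as.double(translation)),
            class = "camera_pose")
}

#' Random camera pose emulating a ceiling-mounted depth camera
#'
#' Draws a rotation composed of an arbitrary yaw about the vertical axis and a
#' bounded tilt about a random horizontal axis, plus a translation. The tilt
#' bound keeps both the seat surface and the (already tilted) backrest
#' representable by the `z = f(x, y)` plane parameterization used by
#' [fit_seat_plane()]; a camera near the ceiling looking broadly downward
#' satisfies this in practice.
#'
#' @param seed Integer seed.
#' @param max_tilt Maximum tilt from vertical (rad); default 12 degrees.
#' @param translation_sd Standard deviation of each translation component (m).
#' @return A `camera_pose`.
#' @export
random_camera_pose <- function(seed, max_tilt = 12 * pi / 180, translation_sd = 1) {
  with_seed(seed, {
    yaw <- stats::runif(1, 0, 2 * pi)
    tilt <- stats::runif(1, 0, max_tilt)
    axis_ang <- stats::runif(1, 0, 2 * pi)
    tr <- stats::rnorm(3, sd = translation_sd)
    Rz <- rotation_about(c(0, 0, 1), yaw)
    axis <- c(cos(axis_ang), sin(axis_ang), 0)
    Rt <- rotation_about(axis, tilt)
    camera_pose(Rt %*% Rz, tr)
  })
}

# Rodrigues rotation about a unit axis.
rotation_about <- function(axis, angle) {
  axis <- unitize(axis)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Standing-behavior archetype specification
#'
#' Parameterizes one of two sit-to-stand archetypes observed in natural
#' behavior:
#'
#' * `armrest_assisted` — the person sits next to the standing aid, places a
#'   hand on the armrest/handrail during the transition, and rises with little
#'   forward trunk lean;
#' * `forward_lean` — the person sits away from the standing aid (e.g. near
#'   the center of a sofa), puts the hands on the knees, and rises by pitching
#'   the trunk strongly forward.
#'
#' Defaults place the two archetypes at their full contrast; `separation`
#' scales that contrast from 0 (identical kinematics) to 1 (full contrast),
#' which is useful for studying when downstream clustering stops resolving
#' them. Under the defaults `forward_lean` has a strictly larger trunk pitch
#' peak and shoulder forward excursion than `armrest_assisted`.
#'
#' @param archetype `"armrest_assisted"` or `"forward_lean"`.
#' @param duration_frames Number of frames (>= 10) of the rendered trial.
#' @param trunk_pitch_peak Peak forward trunk pitch during the transition (rad).
#' @param shoulder_forward_excursion Peak forward shoulder travel beyond the
#'   seated position during the transition (m).
#' @param hand_target Where the hands go during the transition:
#'   `"armrest_anchor"` or `"knees"`.
#' @param anchor_gap Seated distance of the hip center from the armrest base
#'   along the seat width (m).
#' @param noise_sd Isotropic Gaussian jitter added to every joint coordinate (m).
#' @param seed Integer seed for the jitter.
#' @param separation Contrast scale in `[0, 1]` used to fill unspecified
#'   `forward_lean` parameters (see Details).
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(archetype = c("armrest_assisted", "forward_lean"),
                           duration_frames = 100L,
                           trunk_pitch_peak = NULL,
                           shoulder_forward_excursion = NULL,
                           hand_target = NULL,
                           anchor_gap = NULL,
                           noise_sd = 0.01,
                           seed = 1L,
                           separation = 1) {
  archetype <- match.arg(archetype)
  if (!is.numeric(separation) || separation < 0 || separation > 1) {
    stop("separation must be in [0, 1]")
  }
  # armrest_assisted baseline; forward_lean departs from it by `separation`
  # times the full-contrast deltas.
  base <- list(pitch = 0.15, exc = 0.05, gap = 0.25)
  delta <- list(pitch = 0.45, exc = 0.20, gap = 0.35)
  s <- if (archetype == "forward_lean") separation else 0
  spec <- list(
    archetype = archetype,
    duration_frames = as.integer(duration_frames),
    trunk_pitch_peak = trunk_pitch_peak %||% (base$pitch + s * delta$pitch),
    shoulder_forward_excursion =
      shoulder_forward_excursion %||% (base$exc + s * delta$exc),
    hand_target = hand_target %||%
      if (archetype == "forward_lean" && separation > 0) "knees" else "armrest_anchor",
    anchor_gap = anchor_gap %||% (base$gap + s * delta$gap),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (spec$duration_frames < 10L) stop("duration_frames must be >= 10")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (!spec$hand_target %in% c("armrest_anchor", "knees")) {
    stop("hand_target must be 'armrest_anchor' or 'knees'")
  }
  structure(spec, class = "archetype_spec")
}
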