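# The synthetic 24-trial behavior library: same composition as the recorded
# elderly-behavior study (6 participants; chairs, sofas and nursing beds;
# Barthel Index and MMSE per participant), with the two-archetype structure
# reported there planted in the kinematics.

#' Trial metadata of the 24-trial study composition
#'
#' Returns the trial table the synthetic library reproduces: 24 sit-to-stand
#' trials of 6 elderly participants, with participant sex, Barthel Index (BI,
#' physical-ability score 0-100), MMSE (cognitive-ability score 0-30) and the
#' seat used (5 nursing-bed, 8 chair and 11 sofa trials).
#'
#' @return A data.frame with columns `trial_id`, `participant_id`, `sex`,
#'   `BI`, `MMSE`, `product`.
#' @export
study_metadata <- function() {
  rows <- list(
    c("no9_1", "M", 55, 22, "nursing_bed"),
    c("no9_2", "M", 55, 22, "nursing_bed"),
    c("no9_3", "M", 55, 22, "nursing_bed"),
    c("no9_4", "M", 55, 22, "nursing_bed"),
    c("no9_5", "M", 55, 22, "nursing_bed"),
    c("no29_1", "F", 85, 19, "chair"),
    c("no29_2", "F", 85, 19, "chair"),
    c("no29_3", "F", 85, 19, "chair"),
    c("no29_4", "F", 85, 19, "chair"),
    c("no30_1", "M", 80, 24, "sofa"),
    c("no30_2", "M", 80, 24, "sofa"),
    c("no30_3", "M", 80, 24, "chair"),
    c("no30_4", "M", 80, 24, "sofa"),
    c("no31_1", "F", 55, 6, "chair"),
    c("no31_2", "F", 55, 6, "sofa"),
    c("no31_3", "F", 55, 6, "chair"),
    c("no31_4", "F", 55, 6, "sofa"),
    c("no32_1", "M", 55, 17, "sofa"),
    c("no32_2", "M", 55, 17, "sofa"),
    c("no32_3", "M", 55, 17, "sofa"),
    c("no33_1", "F", 55, 15, "sofa"),
    c("no33_2", "F", 55, 15, "chair"),
    c("no33_3", "F", 55, 15, "sofa"),
    c("no33_4", "F", 55, 15, "sofa")
  )
  m <- do.call(rbind, rows)
  data.frame(
    trial_id = m[, 1],
    participant_id = sub("_[0-9]+$", "", m[, 1]),
    sex = m[, 2],
    BI = as.integer(m[, 3]),
    MMSE = as.integer(m[, 4]),
    product = m[, 5],
    stringsAsFactors = FALSE
  )
}

# The two trials carrying the forward-lean archetype (sofa trials where the
# sitter stood up away from the armrest).
FORWARD_LEAN_TRIALS <- c("no31_4", "no32_2")

#' Simulate the 24-trial behavior library
#'
#' Generates one synthetic trial per row of [study_metadata()]: a seat scan
#' (under a per-trial random ceiling-camera pose) and a camera-frame skeleton
#' sequence of the sit-to-stand. Trials `no31_4` and `no32_2` are rendered
#' with the `forward_lean` archetype; the other 22 with `armrest_assisted`.
#' Trial durations are drawn uniformly from 60-150 frames (about 2-5 s at a
#' depth camera's 30 fps). All randomness (poses, durations, jitter) derives
#' deterministically from `seed`.
#'
#' @param seed Integer master seed.
#' @param noise_sd Joint-jitter and scan-noise standard deviation (m).
#' @param separation Archetype contrast in `[0, 1]`; see [archetype_spec()].
#' @param n_points Points per seat-scan patch.
#' @return An object of class `behavior_library`: a list with `metadata`
#'   (the trial table plus an `archetype` column) and `trials`, a named list
#'   of `list(sequence, scan, archetype)` per trial.
#' @export
simulate_library <- function(seed = 1L, noise_sd = 0.01, separation = 1,
                             n_points = 800L) {
  meta <- study_metadata()
  n <- nrow(meta)
  seeds <- derive_seeds(seed, 3L * n)
  durations <- with_seed(seeds[1], sample(60:150, n, replace = TRUE))

  trials <- vector("list", n)
  names(trials) <- meta$trial_id
  meta$archetype <- ifelse(meta$trial_id %in% FORWARD_LEAN_TRIALS,
                           "forward_lean", "armrest_assisted")
  for (i in seq_len(n)) {
    seat <- seat_spec(meta$product[i])
    pose <- random_camera_pose(seeds[n + i])
    arch <- archetype_spec(
      meta$archetype[i],
      duration_frames = durations[i],
      noise_sd = noise_sd,
      seed = seeds[2L * n + i],
      separation = separation
    )
    scan <- generate_seat_scan(seat, pose, noise_sd = noise_sd,
                               n_points = n_points, seed = seeds[2L * n + i])
    seqc <- generate_standing_behavior(arch, seat, pose,
                                       trial_id = meta$trial_id[i])
    trials[[i]] <- list(sequence = seqc, scan = scan,
                        archetype = meta$archetype[i])
  }
  structure(list(metadata = meta, trials = trials, seed = as.integer(seed)),
            class = "behavior_library")
}

#' @export
print.behavior_library <- function(x, ...) {
  cat(sprintf("<behavior_library> %d trials, %d participants (seed %d)\n",
              nrow(x$metadata), length(unique(x$metadata$participant_id)),
              x$seed))
  print(table(x$metadata$product))
  invisible(x)
}
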