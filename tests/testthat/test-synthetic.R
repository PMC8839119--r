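# Synthetic seat scans, standing behaviors and the 24-trial library.

test_that("identity-pose noiseless scan lies exactly on the seat plane with the annotated anchor", {
  spec <- seat_spec("chair")
  scan <- generate_seat_scan(spec, camera_pose(), noise_sd = 0, seed = 3)
  expect_equal(unname(scan$surface_points[, 3]),
               rep(spec$seat_height, nrow(scan$surface_points)))
  expect_equal(scan$anchor_point,
               c(0, 0, spec$seat_height) + spec$anchor_offset)
})

test_that("a rigid camera move preserves all pairwise distances in a noiseless scan", {
  spec <- seat_spec("sofa")
  s0 <- generate_seat_scan(spec, camera_pose(), noise_sd = 0, n_points = 200, seed = 5)
  pose <- random_camera_pose(7)
  s1 <- generate_seat_scan(spec, pose, noise_sd = 0, n_points = 200, seed = 5)
  for (patch in c("surface_points", "reference_points")) {
    d0 <- dist(s0[[patch]])
    d1 <- dist(s1[[patch]])
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("generator output is bit-identical under the same seed", {
  spec <- seat_spec("nursing_bed")
  pose <- random_camera_pose(11)
  s1 <- generate_seat_scan(spec, pose, noise_sd = 0.01, seed = 42)
  s2 <- generate_seat_scan(spec, pose, noise_sd = 0.01, seed = 42)
  expect_identical(s1$surface_points, s2$surface_points)
  arch <- archetype_spec("forward_lean", seed = 42)
  b1 <- generate_standing_behavior(arch, spec, pose)
  b2 <- generate_standing_behavior(arch, spec, pose)
  expect_identical(b1$frames, b2$frames)
  expect_error(generate_seat_scan(spec, list(rotation = diag(2)), seed = 1),
               "camera_pose")
})

test_that("armrest-assisted hand reaches the standing aid; forward lean has larger shoulder excursion", {
  seat <- seat_spec("sofa")
  pose <- camera_pose()
  arm <- generate_standing_behavior(
    archetype_spec("armrest_assisted", noise_sd = 0, seed = 1), seat, pose)
  fwd <- generate_standing_behavior(
    archetype_spec("forward_lean", noise_sd = 0, seed = 1), seat, pose)

  anchor <- c(0, 0, seat$seat_height) + seat$anchor_offset
  wrist_dist <- apply(arm$frames[, "left_wrist", ], 1,
                      function(p) sqrt(sum((p - anchor)^2)))
  expect_lt(min(wrist_dist), 0.05)

  excursion <- function(seq) {
    x <- seq$truth$object_frames[, "left_shoulder", 1]
    max(x) - x[1]
  }
  expect_gt(excursion(fwd), excursion(arm))
})

test_that("the same seeded behavior under two camera poses is one rigid transform apart", {
  seat <- seat_spec("chair")
  arch <- archetype_spec("armrest_assisted", noise_sd = 0.01, seed = 9)
  bA <- generate_standing_behavior(arch, seat, random_camera_pose(1))
  bB <- generate_standing_behavior(arch, seat, random_camera_pose(2))
  t_mid <- 50
  dA <- dist(bA$frames[t_mid, , ])
  dB <- dist(bB$frames[t_mid, , ])
  expect_lt(max(abs(dA - dB)), 1e-9)
  # ground truth is pose-independent by construction
  expect_equal(bA$truth$object_frames, bB$truth$object_frames, tolerance = 1e-12)
})

test_that("the 24-trial library reproduces the study composition", {
  lib <- simulate_library(seed = 123)
  meta <- lib$metadata
  expect_equal(nrow(meta), 24L)
  expect_equal(length(unique(meta$participant_id)), 6L)
  counts <- table(meta$product)
  expect_equal(unname(counts[c("nursing_bed", "chair", "sofa")]),
               c(5L, 8L, 11L), ignore_attr = TRUE)
  expect_setequal(unique(meta$BI), c(55L, 80L, 85L))
  expect_true(all(meta$MMSE >= 0 & meta$MMSE <= 30))
  fwd <- meta$trial_id[meta$archetype == "forward_lean"]
  expect_setequal(fwd, c("no31_4", "no32_2"))
  durations <- vapply(lib$trials, function(tr) dim(tr$sequence$frames)[1],
                      integer(1))
  expect_true(all(durations >= 60 & durations <= 150))
})

test_that("shrinking the archetype separation closes the between/within distance gap monotonically", {
  gap_at <- function(separation) {
    lib <- simulate_library(seed = 4, separation = separation)
    frames <- lapply(lib$trials, function(tr) object_frame_from_scan(tr$scan, tr$sequence))
    rs <- lapply(Map(normalize_sequence, lapply(lib$trials, `[[`, "sequence"),
                     frames), resample_sequence, n_out = 200)
    D <- distance_matrix(rs)$total
    fwd <- lib$metadata$archetype == "forward_lean"
    between <- mean(D[fwd, !fwd])
    within <- mean(D[!fwd, !fwd][upper.tri(D[!fwd, !fwd])])
    between - within
  }
  gaps <- vapply(c(1, 0.5, 0.2, 0), gap_at, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(abs(gaps[4]), 0.15 * gaps[1])
})
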