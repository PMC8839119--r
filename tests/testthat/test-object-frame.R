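# Plane fitting, basis construction, the rigid camera-to-object transform,
# and the camera-pose invariance it exists to deliver.

test_that("noiseless plane fits are exact", {
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  f <- fit_seat_plane(flat)
  expect_equal(c(f$a, f$b, f$d), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(f$rms_residual, 0, tolerance = 1e-12)

  # Z = -(0.1 X - 0.2 Y + 0.5)
  pts <- rbind(c(0, 0, -0.5), c(1, 0, -0.6), c(0, 1, -0.3), c(1, 1, -0.4))
  f2 <- fit_seat_plane(pts)
  expect_equal(c(f2$a, f2$b, f2$d), c(0.1, -0.2, 0.5), tolerance = 1e-12)
  expect_equal(f2$c, 1)
})

test_that("noisy plane fit matches the closed-form normal-equations oracle", {
  stsmap:::with_seed(31, {
    X <- runif(1000, -0.5, 0.5)
    Y <- runif(1000, -0.5, 0.5)
    Z <- -(0.12 * X - 0.07 * Y + 0.4) + rnorm(1000, sd = 0.005)
    f <- fit_seat_plane(cbind(X, Y, Z))
    A <- cbind(X, Y, 1)
    coef_oracle <- solve(crossprod(A), -crossprod(A, Z))
    expect_equal(c(f$a, f$b, f$d), as.vector(coef_oracle), tolerance = 1e-9)
  })
})

test_that("degenerate inputs are rejected with explicit errors", {
  line <- cbind(seq(0, 1, length.out = 20), seq(0, 2, length.out = 20), 0.3)
  expect_error(fit_seat_plane(line), "collinear")
  stsmap:::with_seed(8, {
    vertical <- cbind(0.02 * rnorm(50), runif(50), runif(50))
    expect_error(fit_seat_plane(vertical), "vertical")
  })
  expect_error(fit_seat_plane(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
})

test_that("fitted seat normal recovers the ground truth within 1 degree at 5 mm noise", {
  spec <- seat_spec("chair")
  pose <- random_camera_pose(7)
  scan <- generate_seat_scan(spec, pose, noise_sd = 0.005, n_points = 1000, seed = 7)
  f <- fit_seat_plane(scan$surface_points)
  est <- f$normal / sqrt(sum(f$normal^2))
  truth <- scan$truth$normal_camera
  ang <- acos(min(1, abs(sum(est * truth)))) * 180 / pi
  expect_lt(ang, 1.0)
})

test_that("basis construction orthogonalizes the backrest direction", {
  mkfit <- function(normal) {
    # build a plane_fit whose [a, b, 1] direction matches `normal`
    structure(list(a = normal[1] / normal[3], b = normal[2] / normal[3], c = 1,
                   d = 0, normal = c(normal[1] / normal[3], normal[2] / normal[3], 1),
                   rms_residual = 0, n_points = 4L), class = "plane_fit")
  }
  b <- build_basis(mkfit(c(0, 0, 1)), mkfit(c(1, 0, 1e6)))
  expect_equal(b$ey, c(0, 1, 0), tolerance = 1e-6)
  expect_equal(b$ex, c(1, 0, 0), tolerance = 1e-6)

  # an out-of-plane component in ex_raw is removed by re-orthogonalization
  b2 <- build_basis(mkfit(c(0, 0, 1)), mkfit(c(1, 0, 0.5)))
  expect_equal(b2$ey, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(b2$ex, c(1, 0, 0), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(b2$ex_raw, b2$ex)))

  expect_error(build_basis(mkfit(c(0, 0, 1)), mkfit(c(0, 0, 1))), "parallel")
})

test_that("a rotated seat yields the rotated canonical basis", {
  spec <- seat_spec("sofa")
  pose <- random_camera_pose(11)
  scan <- generate_seat_scan(spec, pose, noise_sd = 0, n_points = 500, seed = 11)
  arch <- archetype_spec("armrest_assisted", noise_sd = 0, seed = 11)
  hint <- generate_standing_behavior(arch, spec, pose)
  fr <- object_frame_from_scan(scan, hint)
  Q <- pose$rotation
  expect_equal(fr$ex, unname(Q[, 1]), tolerance = 1e-6)
  expect_equal(fr$ey, unname(Q[, 2]), tolerance = 1e-6)
  expect_equal(fr$ez, unname(Q[, 3]), tolerance = 1e-6)
})

test_that("make_transform builds a rigid, invertible camera-to-object map", {
  basis <- list(ex = c(1, 0, 0), ey = c(0, 1, 0), ez = c(0, 0, 1))
  fr <- make_transform(basis, c(1, 2, 3))
  expect_equal(transform_points(fr, rbind(c(1, 2, 3)))[1, ], c(0, 0, 0),
               tolerance = 1e-15)

  pose <- random_camera_pose(21)
  fr2 <- make_transform(list(ex = pose$rotation[, 1], ey = pose$rotation[, 2],
                             ez = pose$rotation[, 3]), c(0.3, -0.2, 1.1))
  expect_lt(max(abs(fr2$R %*% t(fr2$R) - diag(3))), 1e-9)
  expect_equal(det(fr2$R), 1, tolerance = 1e-9)

  stsmap:::with_seed(22, {
    p <- matrix(rnorm(300), 100, 3)
    q <- matrix(rnorm(300), 100, 3)
    tp <- transform_points(fr2, p)
    tq <- transform_points(fr2, q)
    expect_lt(max(abs(sqrt(rowSums((p - q)^2)) - sqrt(rowSums((tp - tq)^2)))), 1e-12)
    # round trip through H and its inverse
    Hinv <- solve(fr2$H)
    ph <- cbind(tp, 1) %*% t(Hinv)
    expect_lt(max(abs(ph[, 1:3] - p)), 1e-12)
  })

  expect_error(make_transform(list(ex = c(1, 0, 0), ey = c(1, 0, 0),
                                   ez = c(0, 0, 1)), c(0, 0, 0)),
               "orthonormal")
})

test_that("normalization maps the anchor to the origin and is the identity for the identity frame", {
  seat <- seat_spec("chair")
  arch <- archetype_spec("armrest_assisted", noise_sd = 0, seed = 2)
  seqc <- generate_standing_behavior(arch, seat, camera_pose())
  id_frame <- make_transform(list(ex = c(1, 0, 0), ey = c(0, 1, 0),
                                  ez = c(0, 0, 1)), c(0, 0, 0))
  out <- normalize_sequence(seqc, id_frame)
  expect_equal(out$frames, seqc$frames, tolerance = 1e-15)
  expect_identical(out$coordinate_frame, "object")
  expect_error(normalize_sequence(out, id_frame), "already")

  scan <- generate_seat_scan(seat, camera_pose(), noise_sd = 0, seed = 2)
  fr <- object_frame_from_scan(scan, seqc)
  expect_equal(transform_points(fr, rbind(scan$anchor_point))[1, ], c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("normalized trajectories are invariant to the camera pose", {
  seat <- seat_spec("nursing_bed")
  arch <- archetype_spec("forward_lean", noise_sd = 0, seed = 17)
  norm_render <- function(pose_seed) {
    pose <- random_camera_pose(pose_seed)
    scan <- generate_seat_scan(seat, pose, noise_sd = 0, seed = 17)
    seqc <- generate_standing_behavior(arch, seat, pose)
    normalize_sequence(seqc, object_frame_from_scan(scan, seqc))
  }
  a <- norm_render(101)
  b <- norm_render(202)
  expect_lt(max(abs(a$frames - b$frames)), 1e-6)
  # and both agree with the generator's stored ground truth
  expect_lt(max(abs(a$frames - a$truth$object_frames)), 1e-6)
})
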