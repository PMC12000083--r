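test_that("single-axis rotations and the Cardan composition match explicit matrices", {
  expect_equal(cardan_to_matrix(c(0, 0, 0)), diag(3))
  # Rx(90) maps the y-axis onto the z-axis
  expect_equal(cardan_to_matrix(c(90, 0, 0)),
               matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, byrow = TRUE),
               tolerance = 1e-12)
  # oracle: compose three independently written single-axis matrices
  set.seed(1)
  for (i in 1:20) {
    a <- runif(3, -pi, pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
    Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
    Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
    expect_equal(cardan_to_matrix(a * 180 / pi), Rx %*% Ry %*% Rz,
                 tolerance = 1e-12)
  }
  expect_error(cardan_to_matrix(c(1, NA, 0)),
               class = "reframekin_invalid_argument")
})

test_that("Cardan round trip is exact to 1e-9 away from gimbal lock", {
  expect_equal(unname(matrix_to_cardan(diag(3))), c(0, 0, 0))
  expect_equal(unname(matrix_to_cardan(cardan_to_matrix(c(-60, 5, -8)))),
               c(-60, 5, -8), tolerance = 1e-9)
  set.seed(7)
  for (i in 1:1000) {
    tr <- random_triplet(85)
    back <- matrix_to_cardan(cardan_to_matrix(tr))
    expect_lt(max(abs(unname(back) - tr)), 1e-9)
    # matrix round trip too
    expect_lt(max(abs(cardan_to_matrix(back) - cardan_to_matrix(tr))), 1e-12)
  }
})

test_that("gimbal proximity raises a degenerate-orientation condition with its resolution", {
  R <- cardan_to_matrix(c(10, 89.999999, 5))
  err <- tryCatch(matrix_to_cardan(R), condition = function(c) c)
  expect_s3_class(err, "reframekin_gimbal_error")
  expect_length(err$resolution, 3)
  expect_equal(err$resolution[3], 0)   # gamma folded away
  # resolution reproduces the matrix up to the degenerate direction
  expect_equal(err$resolution[2], 90, tolerance = 1e-4)
  # comfortably away from lock: no condition
  expect_silent(matrix_to_cardan(cardan_to_matrix(c(10, 89, 5))))
})

test_that("joint_rotation is the femur-to-tibia change of basis and is equivariant", {
  R <- cardan_to_matrix(c(-30, 4, 12))
  expect_equal(joint_rotation(R, R), diag(3), tolerance = 1e-12)
  expect_equal(joint_rotation(diag(3), rot_z(10)), rot_z(10), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:200) {
    fem <- cardan_to_matrix(random_triplet())
    tib <- cardan_to_matrix(random_triplet())
    J <- joint_rotation(fem, tib)
    # oracle: project tibial axes onto femoral axes
    oracle <- matrix(0, 3, 3)
    for (r in 1:3) for (cc in 1:3)
      oracle[r, cc] <- sum(fem[, r] * tib[, cc])
    expect_lt(max(abs(J - oracle)), 1e-12)
    # equivariance under a common lab-frame pre-rotation
    G <- cardan_to_matrix(random_triplet())
    expect_lt(max(abs(joint_rotation(G %*% fem, G %*% tib) - J)), 1e-9)
  }
})

test_that("mirroring is an involution that negates beta_y and gamma_z only", {
  # pure flexion is invariant under sagittal mirroring
  Rf <- cardan_to_matrix(c(-60, 0, 0))
  expect_equal(mirror_left_to_right(Rf), Rf, tolerance = 1e-12)
  # 5 deg adduction flips sign; oracle = mirror the frame axis vectors
  Ra <- cardan_to_matrix(c(0, 5, 0))
  M <- diag(c(-1, 1, 1))
  expect_equal(unname(matrix_to_cardan(M %*% Ra %*% M)), c(0, -5, 0),
               tolerance = 1e-9)
  set.seed(3)
  for (i in 1:200) {
    tr <- random_triplet(80)
    R <- cardan_to_matrix(tr)
    Rm <- mirror_left_to_right(R)
    expect_equal(det(Rm), 1, tolerance = 1e-12)
    expect_equal(unname(matrix_to_cardan(Rm)), c(tr[1], -tr[2], -tr[3]),
                 tolerance = 1e-9)
    # involution
    expect_lt(max(abs(mirror_left_to_right(Rm) - R)), 1e-12)
  }
  # point mirroring flips x only
  pts <- matrix(rnorm(30), ncol = 3)
  mp <- mirror_left_to_right(pts, kind = "points")
  expect_equal(mp[, 1], -pts[, 1])
  expect_equal(mp[, 2:3], pts[, 2:3])
})

test_that("left-side pose series mirror once and refuse double mirroring", {
  R <- array(rep(diag(3), 5), c(3, 3, 5))
  ps <- pose_series(R, 100, seg = "tibia", side = "L")
  m <- mirror_left_to_right(ps)
  expect_true(m$mirrored)
  expect_error(mirror_left_to_right(m), class = "reframekin_invalid_state")
  right <- pose_series(R, 100, seg = "tibia", side = "R")
  expect_error(mirror_left_to_right(right),
               class = "reframekin_invalid_state")
})

test_that("compute_joint_angles extracts relative Cardan series", {
  n <- 50L
  I3 <- array(rep(diag(3), n), c(3, 3, n))
  fem <- pose_series(I3, 100, seg = "femur")
  tib <- pose_series(I3, 100, seg = "tibia")
  ja <- compute_joint_angles(fem, tib)
  expect_equal(max(abs(ja$angles)), 0)
  # constant flexion offset by construction
  Rflex <- rot_x(-60)
  Tb <- array(vapply(seq_len(n), function(i) I3[, , i] %*% Rflex,
                     matrix(0, 3, 3)), c(3, 3, n))
  ja2 <- compute_joint_angles(fem, pose_series(Tb, 100, seg = "tibia"))
  expect_equal(unname(ja2$angles[, 1]), rep(-60, n), tolerance = 1e-9)
  expect_equal(unname(to_clinical_display(ja2)$flex_deg), rep(60, n),
               tolerance = 1e-9)
  # length mismatch
  short <- pose_series(I3[, , 1:10], 100, seg = "tibia")
  expect_error(compute_joint_angles(fem, short),
               class = "reframekin_invalid_argument")
})

test_that("angle extraction recovers the generator's ground truth exactly when unperturbed", {
  cfg <- tiny_config()
  truth <- generate_base_motion(cfg, 99L)[[1]]
  obs <- observe_through_marker_set(truth,
                                    list(fem = c(0, 0, 0), tib = c(0, 0, 0)),
                                    cfg, sta_scale = 0)
  ja <- compute_joint_angles(obs$femur, obs$tibia)
  expect_lt(max(abs(ja$angles - truth$angles)), 1e-9)
})

test_that("unwrapping keeps channels continuous across the +/-180 boundary", {
  g <- seq(160, 200, length.out = 40)          # crosses +180
  T <- cardan_to_matrix(c(0, 0, 0))
  arr <- array(vapply(g, function(x) rot_z(x), matrix(0, 3, 3)), c(3, 3, 40))
  ja <- compute_joint_angles(array(rep(diag(3), 40), c(3, 3, 40)), arr)
  expect_lt(max(abs(diff(ja$angles[, 3]))), 2)  # no 360 jumps
  expect_equal(unname(ja$angles[40, 3]), 200, tolerance = 1e-9)
})

test_that("clinical display flips only the flexion sign and round-trips", {
  ja <- joint_angles(cbind(c(-10, -60), c(1, 2), c(-3, 4)))
  disp <- to_clinical_display(ja)
  expect_equal(disp$flex_deg, c(10, 60))
  expect_equal(disp$add_deg, c(1, 2))
  expect_equal(disp$introt_deg, c(-3, 4))
  expect_equal(-disp$flex_deg, unname(ja$angles[, 1]))  # stored data unchanged
})

test_that("gait-cycle normalization interpolates linearly onto 0-100%", {
  n <- 220L
  const <- joint_angles(cbind(rep(-20, n), 1, 2), domain_type = "frame",
                        rate_hz = 200)
  out <- normalize_gait_cycle(const, c(1L, n))
  expect_length(out, 1)
  expect_equal(nrow(out[[1]]$angles), 101)
  expect_equal(out[[1]]$domain, seq(0, 100, length.out = 101))
  expect_equal(max(abs(sweep(out[[1]]$angles, 2, c(-20, 1, 2)))), 0)
  # linear ramp is reproduced exactly
  ramp <- joint_angles(cbind(seq(0, 10, length.out = n), 0, 0),
                       domain_type = "frame", rate_hz = 200)
  r <- normalize_gait_cycle(ramp, c(1L, n))[[1]]
  expect_equal(unname(r$angles[, 1]), seq(0, 10, length.out = 101),
               tolerance = 1e-12)
  # sinusoid at 200 Hz vs analytic resample: < 0.05 deg at 101 points
  p <- (seq_len(n) - 1) / (n - 1)
  sine <- joint_angles(cbind(60 * sin(2 * pi * p), 0, 0),
                       domain_type = "frame", rate_hz = 200)
  s <- normalize_gait_cycle(sine, c(1L, n))[[1]]
  expect_lt(max(abs(s$angles[, 1] - 60 * sin(2 * pi * s$domain / 100))), 0.05)
  # monotone segment keeps its min/max within interpolation tolerance
  mono <- joint_angles(cbind(cumsum(runif(n)), 0, 0), domain_type = "frame",
                       rate_hz = 200)
  m <- normalize_gait_cycle(mono, c(1L, n))[[1]]
  expect_equal(range(m$angles[, 1]), range(mono$angles[, 1]),
               tolerance = 1e-9)
  # two cycles produce two series
  two <- normalize_gait_cycle(const, c(1L, 110L, n))
  expect_length(two, 2)
  expect_error(normalize_gait_cycle(const, c(5L)),
               class = "reframekin_invalid_argument")
})
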