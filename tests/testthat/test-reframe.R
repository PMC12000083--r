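test_that("the cost is the stated weighted sum of per-channel RMS/RMSE terms", {
  n <- 64L
  zero <- cbind(rep(-30, n), 0, 0)
  expect_identical(reframe_cost(zero, zero[, 1]), 0)
  # constant 3 deg ab/adduction and 4 deg rotation, flexion on reference
  m <- cbind(rep(-30, n), 3, 4)
  expect_equal(reframe_cost(m, m[, 1]), 7, tolerance = 1e-12)
  # random series against independent per-channel metrics
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(rnorm(3 * n, sd = 10), ncol = 3)
    ref <- rnorm(n, sd = 10)
    cfg <- reframe_config(w_add = runif(1), w_introt = runif(1),
                          w_flex = runif(1))
    expect_equal(reframe_cost(m, ref, cfg),
                 cfg$w_add * rms(m[, 2]) + cfg$w_introt * rms(m[, 3]) +
                   cfg$w_flex * rmse(m[, 1], ref),
                 tolerance = 1e-12)
  }
  expect_error(reframe_cost(m, ref[1:10]),
               class = "reframekin_invalid_argument")
  expect_error(reframe_config(w_add = 0, w_introt = 0),
               class = "reframekin_invalid_argument")
  expect_error(reframe_config(w_add = -1),
               class = "reframekin_invalid_argument")
})

test_that("frame corrections act as transpose(R_fem) T R_tib, matching the pose pipeline", {
  tr <- observed_trial(list(fem = c(0, 0, 0), tib = c(0, 0, 10)))$normalized
  # identity corrections leave the series unchanged
  same <- apply_frame_corrections(tr, diag(3), diag(3))
  expect_lt(max(abs(same$angles - tr$angles)), 1e-9)
  # exact cancellation of a pre-rotated tibial frame
  fixed <- apply_frame_corrections(tr, diag(3), rot_z(-10))
  expect_lt(max(abs(fixed$angles[, 3])), 1e-9)
  # random corrections vs recomputing angles from corrected segment poses
  cfg <- tiny_config()
  truth <- generate_base_motion(cfg, 8L)[[1]]
  obs <- observe_through_marker_set(truth,
                                    list(fem = c(1, -2, 5), tib = c(0, 3, -7)),
                                    cfg, sta_scale = 0)
  ja <- compute_joint_angles(obs$femur, obs$tibia)
  set.seed(5)
  for (i in 1:10) {
    Rf <- cardan_to_matrix(random_triplet(20))
    Rt <- cardan_to_matrix(random_triplet(20))
    got <- apply_frame_corrections(ja, Rf, Rt)
    n <- dim(obs$femur$R)[3]
    fem2 <- array(vapply(1:n, function(s) obs$femur$R[, , s] %*% Rf,
                         matrix(0, 3, 3)), c(3, 3, n))
    tib2 <- array(vapply(1:n, function(s) obs$tibia$R[, , s] %*% Rt,
                         matrix(0, 3, 3)), c(3, 3, n))
    oracle <- compute_joint_angles(fem2, tib2)
    expect_lt(max(abs(got$angles - oracle$angles)), 1e-8)
  }
  expect_error(apply_frame_corrections(ja, diag(3) * 2, diag(3)),
               class = "reframekin_invalid_argument")
})

test_that("an already-optimal series yields near-identity corrections", {
  tr <- observed_trial(list(fem = c(0, 0, 0), tib = c(0, 0, 0)))$normalized
  res <- reframe(tr, tr$angles[, 1])
  expect_lt(rotation_angle_deg(res$R_fem_corr), 0.01)
  expect_lt(rotation_angle_deg(res$R_tib_corr), 0.01)
  expect_lt(res$cost_final, 1e-3)
  expect_true(res$converged)
  expect_lte(res$cost_final, res$cost_initial)
})

test_that("imposed constant misalignments are cancelled on noiseless data", {
  mis <- list(fem = c(0, -3, 8), tib = c(0, 2, -11))
  ot <- observed_trial(mis)
  ref_flex <- -gait_flexion_deg(ot$normalized$domain / 100)
  res <- reframe(ot$normalized, ref_flex)
  # net residual frame error (gauge-invariant): both residuals must agree
  Ef <- cardan_to_matrix(mis$fem) %*% res$R_fem_corr
  Et <- cardan_to_matrix(mis$tib) %*% res$R_tib_corr
  net <- matrix_to_cardan(t(Ef) %*% Et)
  expect_lt(max(abs(net)), 0.1)
  expect_lt(rms(res$optimized$angles[, 2]), 0.05)
  expect_lt(rms(res$optimized$angles[, 3]), 0.05)
  # self-consistency: optimized equals re-application of the corrections
  redo <- apply_frame_corrections(ot$normalized, res$R_fem_corr, res$R_tib_corr)
  expect_lt(max(abs(redo$angles - res$optimized$angles)), 1e-9)
})

test_that("the returned corrections are a local minimum of the cost", {
  mis <- list(fem = c(0, 2, -6), tib = c(1, -2, 9))
  ot <- observed_trial(mis, add_amp = 1.5, introt_amp = 2.5)
  ref_flex <- ot$normalized$angles[, 1]
  cfg <- reframe_config()
  res <- reframe(ot$normalized, ref_flex, cfg)
  base <- reframe_cost(res$optimized, ref_flex, cfg)
  for (axis in 1:3) for (side in c("fem", "tib")) for (s in c(-0.5, 0.5)) {
    d <- c(0, 0, 0); d[axis] <- s
    Rf <- res$R_fem_corr; Rt <- res$R_tib_corr
    if (side == "fem") Rf <- Rf %*% cardan_to_matrix(d)
    else Rt <- Rt %*% cardan_to_matrix(d)
    pert <- reframe_cost(apply_frame_corrections(ot$normalized, Rf, Rt),
                         ref_flex, cfg)
    expect_gte(pert, base - 1e-6)
  }
})

test_that("restricted problems match an exhaustive grid search", {
  # two free tibial parameters; brute force over +/-15 deg at 0.5 deg steps
  mis <- list(fem = c(0, 0, 0), tib = c(0, 6.3, -9.7))
  ot <- observed_trial(mis)
  ref_flex <- ot$normalized$angles[, 1]
  cfg <- reframe_config()
  res <- reframe(ot$normalized, ref_flex, cfg, free = c("tib_y", "tib_z"))
  grid <- seq(-15, 15, by = 0.5)
  Tarr <- NULL
  costs <- matrix(NA_real_, length(grid), length(grid))
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    corr <- apply_frame_corrections(ot$normalized, diag(3),
                                    cardan_to_matrix(c(0, grid[i], grid[j])))
    costs[i, j] <- reframe_cost(corr, ref_flex, cfg)
  }
  gmin <- min(costs)
  idx <- which(costs == gmin, arr.ind = TRUE)[1, ]
  # neighbouring-cell cost variation around the grid minimum
  nb <- costs[max(1, idx[1] - 1):min(length(grid), idx[1] + 1),
              max(1, idx[2] - 1):min(length(grid), idx[2] + 1)]
  cell_var <- max(nb) - gmin
  expect_lte(res$cost_final, gmin + 1e-8)
  expect_lte(gmin - res$cost_final, cell_var)
  # the optimum sits inside the grid cell of the imposed inverse
  expect_equal(unname(res$tib_triplet[2]), -6.3, tolerance = 0.5)
  expect_equal(unname(res$tib_triplet[3]), 9.7, tolerance = 0.5)
})

test_that("femoral x-axis restriction modes behave as documented", {
  mis <- list(fem = c(6, -2, 4), tib = c(0, 1, -5))
  ot <- observed_trial(mis)
  ref_flex <- -gait_flexion_deg(ot$normalized$domain / 100)
  locked <- reframe(ot$normalized, ref_flex,
                    reframe_config(femoral_x_mode = "locked"))
  expect_equal(unname(locked$fem_triplet[1]), 0, tolerance = 1e-6)
  bounded <- reframe(ot$normalized, ref_flex,
                     reframe_config(femoral_x_mode = "bounded",
                                    femoral_x_limit_deg = 2))
  expect_lte(abs(bounded$fem_triplet[1]), 2 + 0.05)
  # all modes still drive the crosstalk channels down
  for (r in list(locked, bounded)) {
    expect_lt(rms(r$optimized$angles[, 2]), 0.3)
    expect_lt(rms(r$optimized$angles[, 3]), 0.3)
  }
})

test_that("report_transform uses the intrinsic XYZ convention and round-trips", {
  expect_equal(unname(report_transform(diag(3))), c(0, 0, 0))
  expect_equal(unname(report_transform(rot_z(-6))), c(0, 0, -6),
               tolerance = 1e-9)
  set.seed(13)
  for (i in 1:50) {
    tr <- random_triplet(40)
    expect_equal(unname(report_transform(cardan_to_matrix(tr))), tr,
                 tolerance = 1e-9)
  }
})

test_that("flexion is preserved relative to the reference when w_flex > 0", {
  sets <- list(A = list(fem = c(0, 0, 0), tib = c(0, 0, 0)),
               B = list(fem = c(1, -2, 6), tib = c(0, 2, -9)))
  ref <- observed_trial(sets$A)$normalized
  obs <- observed_trial(sets$B)$normalized
  pre <- rmse(obs$angles[, 1], ref$angles[, 1])
  res <- reframe(obs, ref$angles[, 1])
  post <- rmse(res$optimized$angles[, 1], ref$angles[, 1])
  expect_lte(post, pre + 0.5)
})

test_that("YAML configs mirror reframe_config fields and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("w_flex: 0.3", "reference_label: KAD",
               "femoral_x_mode: locked"), path)
  cfg <- read_reframe_config(path)
  expect_equal(cfg$w_flex, 0.3)
  expect_equal(cfg$reference_label, "KAD")
  expect_equal(cfg$femoral_x_mode, "locked")
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_key: 1", bad)
  expect_error(read_reframe_config(bad),
               class = "reframekin_invalid_argument")
})
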