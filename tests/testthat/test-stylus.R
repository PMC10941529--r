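obs_row <- function(id, frame, time = 0) {
  q <- contourfit:::rotation_to_quat(frame$axes)
  tibble::tibble(time = time, marker_id = id,
                 tx = frame$origin[1], ty = frame$origin[2],
                 tz = frame$origin[3],
                 qw = q[1], qx = q[2], qy = q[3], qz = q[4])
}

two_marker_model <- function() {
  stylus_model(
    list(A = rigid_frame(c(10, 0, 0), cardan_to_rotation(30, 0, 0)),
         B = rigid_frame(c(-10, 5, 0), cardan_to_rotation(0, -45, 10))),
    tip_offset = c(0, 0, 120)
  )
}

test_that("a single identity marker passes the observed pose through", {
  model <- stylus_model(
    list(A = rigid_frame(), B = rigid_frame(c(0, 20, 0), diag(3))),
    tip_offset = c(0, 0, 100)
  )
  P <- rigid_frame(c(5, -2, 400), cardan_to_rotation(10, 20, 30))
  fused <- fuse_body_pose(obs_row("A", P), model)
  expect_equal(fused$frame$origin, P$origin, tolerance = 1e-9)
  expect_equal(fused$frame$axes, P$axes, tolerance = 1e-9)
  expect_identical(fused$n_markers, 1L)
})

test_that("perfectly consistent markers fuse exactly with zero spread", {
  model <- two_marker_model()
  body <- rigid_frame(c(1, 2, 300), cardan_to_rotation(-20, 15, 40))
  obs <- dplyr::bind_rows(
    obs_row("A", contourfit:::frame_compose(body, model$markers$A)),
    obs_row("B", contourfit:::frame_compose(body, model$markers$B))
  )
  fused <- fuse_body_pose(obs, model)
  expect_equal(fused$frame$origin, body$origin, tolerance = 1e-9)
  expect_equal(fused$frame$axes, body$axes, tolerance = 1e-9)
  expect_lt(fused$spread_trans_mm, 1e-9)
  expect_lt(fused$spread_rot_deg, 1e-7)
  # permutation invariance
  fused2 <- fuse_body_pose(obs[2:1, ], model)
  expect_equal(fused2$frame$axes, fused$frame$axes, tolerance = 1e-12)
  # unknown markers only -> no-pose error
  expect_error(fuse_body_pose(dplyr::mutate(obs, marker_id = "Z"), model),
               class = "contourfit_error_no_pose")
})

test_that("multi-marker fusion beats single-marker poses under rotational noise", {
  set.seed(41)
  model <- default_stylus_model(n_markers = 12, seed = 1)
  body <- rigid_frame(c(0, 0, 500), cardan_to_rotation(5, -10, 20))
  n_win <- 0
  n_trials <- 400
  for (trial in seq_len(n_trials)) {
    rows <- lapply(names(model$markers), function(id) {
      pose <- contourfit:::frame_compose(body, model$markers[[id]])
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- rnorm(1, 0, 0.5) * pi / 180
      K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
                 c(-ax[2], ax[1], 0))
      noisy <- (diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)) %*%
        pose$axes
      obs_row(id, rigid_frame(pose$origin, noisy))
    })
    obs <- dplyr::bind_rows(rows)
    fused <- fuse_body_pose(obs, model)
    fused_err <- contourfit:::rotation_angle_deg(fused$frame$axes, body$axes)
    # per-marker oracle: the mean error of the individual candidate poses
    single_err <- mean(vapply(seq_len(nrow(obs)), function(k) {
      cand <- fuse_body_pose(obs[k, ], model)
      contourfit:::rotation_angle_deg(cand$frame$axes, body$axes)
    }, 0))
    if (fused_err < single_err) n_win <- n_win + 1
  }
  expect_gt(n_win / n_trials, 0.9)
})

test_that("noiseless pivot calibration recovers the tip offset exactly", {
  poses <- generate_pivot_poses(c(1.5, -2, 120), c(10, -20, 500),
                                n_poses = 40, seed = 2)
  cal <- pivot_calibrate(poses)
  expect_lt(max(abs(cal$tip_offset - c(1.5, -2, 120))), 1e-9)
  expect_lt(max(abs(cal$pivot_point - c(10, -20, 500))), 1e-9)
  expect_lt(cal$rms, 1e-9)
})

test_that("pure translation is a degenerate pivoting motion", {
  poses <- lapply(1:10, function(i) rigid_frame(c(i, 0, 500), diag(3)))
  expect_error(pivot_calibrate(poses),
               class = "contourfit_error_degenerate_motion")
  expect_error(pivot_calibrate(poses[1:2]),
               class = "contourfit_error_contract")
})

test_that("pivot residual tracks the injected noise level linearly", {
  set.seed(43)
  noise_levels <- c(0.05, 0.1, 0.2, 0.4)
  rms <- vapply(noise_levels, function(s) {
    poses <- generate_pivot_poses(c(0, 0, 120), n_poses = 60,
                                  trans_noise_mm = s)
    pivot_calibrate(poses)$rms
  }, 0)
  # consistency: reported rms close to the injected level
  expect_true(all(rms / noise_levels > 0.5 & rms / noise_levels < 2))
  slope <- coef(lm(rms ~ noise_levels))[2]
  expect_gt(slope, 0.5)
  expect_lt(slope, 2)
})

test_that("tip trajectories are exact for static tools and keep gaps", {
  model <- two_marker_model()
  body <- rigid_frame(c(0, 0, 400), cardan_to_rotation(10, 0, -5))
  tip_true <- as.numeric(body$origin + body$axes %*% model$tip_offset)
  frames <- lapply(1:5, function(i) dplyr::bind_rows(
    obs_row("A", contourfit:::frame_compose(body, model$markers$A), time = i / 10),
    obs_row("B", contourfit:::frame_compose(body, model$markers$B), time = i / 10)
  ))
  stream <- dplyr::bind_rows(frames)
  # knock out every marker of frame 3 -> a gap, not an interpolation
  stream <- stream[!(stream$time == 0.3), ]
  gap_row <- tibble::tibble(time = 0.3, marker_id = NA_character_,
                            tx = NA_real_, ty = NA_real_, tz = NA_real_,
                            qw = NA_real_, qx = NA_real_, qy = NA_real_,
                            qz = NA_real_)
  stream <- dplyr::arrange(dplyr::bind_rows(stream, gap_row), time)
  traj <- tip_trajectory(stream, model)
  expect_identical(nrow(traj), 5L)
  ok <- traj[traj$n_markers > 0, ]
  expect_equal(unname(as.matrix(ok[, c("x", "y", "z")])),
               matrix(tip_true, 4, 3, byrow = TRUE), tolerance = 1e-9)
  expect_true(is.na(traj$x[traj$time == 0.3]))
  expect_identical(traj$n_markers[traj$time == 0.3], 0L)
})

test_that("a synthetic digitalisation sweep is recovered end to end", {
  model <- default_stylus_model(n_markers = 8, seed = 4)
  t <- seq(0, 2 * pi, length.out = 40)
  path <- tibble::tibble(time = seq_along(t) / 10,
                         x = 14.4 * cos(t), y = 10.2 * sin(t), z = 500)
  stream <- generate_marker_stream(path, model, rot_noise_deg = 0,
                                   trans_noise_mm = c(0, 0, 0),
                                   dropout_rate = 0, seed = 5)
  traj <- tip_trajectory(stream, model)
  expect_equal(as.matrix(traj[, c("x", "y", "z")]),
               as.matrix(path[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("full dropout produces an all-gap trajectory", {
  model <- default_stylus_model(n_markers = 4, seed = 6)
  path <- tibble::tibble(time = (1:5) / 10, x = 0, y = 0, z = 300)
  stream <- generate_marker_stream(path, model, dropout_rate = 1, seed = 7)
  traj <- tip_trajectory(stream, model)
  expect_identical(nrow(traj), 5L)
  expect_true(all(is.na(traj$x)))
  expect_true(all(traj$n_markers == 0L))
})

test_that("anisotropic marker noise shows up in the tip scatter", {
  set.seed(44)
  model <- default_stylus_model(n_markers = 12, seed = 8)
  path <- tibble::tibble(time = (1:200) / 10, x = 0, y = 0, z = 500)
  stream <- generate_marker_stream(path, model, rot_noise_deg = 0,
                                   trans_noise_mm = c(0.1, 0.1, 0.3),
                                   wobble_deg = 0, seed = 9)
  traj <- tip_trajectory(stream, model)
  # per-axis scatter of the fused tip: averaging over 12 markers shrinks it
  # by ~sqrt(12); the anisotropy ratio (3x) must survive within a factor 1.5
  sds <- apply(as.matrix(traj[, c("x", "y", "z")]), 2, sd)
  expected <- c(0.1, 0.1, 0.3) / sqrt(12)
  expect_true(all(sds / expected > 1 / 1.5 & sds / expected < 1.5))
})
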