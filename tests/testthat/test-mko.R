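test_that("weight schemes follow the thorax-first ordering and validate", {
  chain <- test_chain()
  w <- default_weights(chain)
  expect_true(w[["SJN"]] > w[["RUAM"]])
  expect_true(w[["RUAM"]] > w[["RFAM"]])
  expect_true(w[["RFAM"]] > w[["RHND"]])
  expect_error(weight_scheme(chain, hand = -1), "non-negative")
})

test_that("a zero-residual configuration is a fixed point of the solver", {
  chain <- test_chain()
  set.seed(21)
  q_star <- guard_posture(chain)
  q_star[7:24] <- q_star[7:24] + stats::runif(18, -0.2, 0.2)
  meas <- project_markers(chain, forward_kinematics(chain, q_star))
  fit <- solve_frame(chain, meas, q_init = q_star)
  expect_lt(fit$report$objective, 1e-16)
  expect_equal(unname(fit$q), unname(q_star), tolerance = 1e-9)
  expect_true(fit$report$converged)
})

test_that("the solver recovers random targets from a guard start (basin check)", {
  chain <- test_chain()
  set.seed(22)
  worst <- 0
  for (k in 1:100) {
    q_star <- guard_posture(chain)
    q_star[7:24] <- q_star[7:24] + stats::runif(18, -pi / 6, pi / 6)
    q_star[1:6] <- stats::runif(6, -0.25, 0.25)
    bounds <- boxkin:::.q_bounds(chain)
    q_star <- pmin(pmax(q_star, bounds$lower), bounds$upper)
    meas <- project_markers(chain, forward_kinematics(chain, q_star))
    fit <- solve_frame(chain, meas, q_init = guard_posture(chain))
    worst <- max(worst, max(abs(fit$q - q_star)))
  }
  expect_lt(worst, 1e-6)
})

test_that("duplicating a marker with halved weights leaves the solution unchanged", {
  chain <- test_chain()
  set.seed(23)
  q_star <- guard_posture(chain)
  q_star[7:24] <- q_star[7:24] + stats::runif(18, -0.25, 0.25)
  meas <- project_markers(chain, forward_kinematics(chain, q_star))
  w <- default_weights(chain)
  base <- solve_frame(chain, meas, weights = w,
                      q_init = guard_posture(chain))

  dup <- chain
  dup$markers$RHND2 <- dup$markers$RHND
  dup$marker_local <- rbind(dup$marker_local,
                            RHND2 = dup$marker_local["RHND", ])
  dup$marker_segment <- c(dup$marker_segment, RHND2 = "hand_R")
  meas2 <- rbind(meas, RHND2 = meas["RHND", ])
  w2 <- c(w, RHND2 = w[["RHND"]] / 2)
  w2[["RHND"]] <- w[["RHND"]] / 2
  split_ <- solve_frame(dup, meas2, weights = w2,
                        q_init = guard_posture(chain))
  expect_equal(unname(split_$q), unname(base$q), tolerance = 1e-8)
})

test_that("marker validation excludes bad input and rejects unsolvable frames", {
  chain <- test_chain()
  q0 <- guard_posture(chain)
  meas <- project_markers(chain, forward_kinematics(chain, q0))
  rownames(meas)[1] <- "MYSTERY"
  expect_warning(fit <- solve_frame(chain, meas, q_init = q0), "unlabeled")
  meas2 <- project_markers(chain, forward_kinematics(chain, q0))
  meas2["RHND", 1] <- NA
  expect_warning(fit2 <- solve_frame(chain, meas2, q_init = q0), "missing")
  expect_false("RHND" %in% names(fit2$report$residual_norms))
  expect_error(
    suppressWarnings(solve_frame(chain, meas2[1:2, ], q_init = q0)),
    "non-collinear")
})

test_that("trajectory solving tracks a noise-free synthetic trial", {
  chain <- test_chain()
  truth <- generate_q_trajectory(chain, short_script(), rate = 150, seed = 3)
  markers <- render_markers(chain, truth)
  sol <- solve_trajectory(chain, markers, q_init = guard_posture(chain))
  expect_equal(n_frames(sol$q_traj), n_frames(markers))
  expect_true(all(sol$q_traj$valid))
  expect_lt(max(abs(sol$q_traj$q - truth$q)), 1e-5)
  # objective is non-increasing across solver iterations
  for (r in sol$reports[c(1, 50, 100)])
    expect_true(all(diff(r$objective_trace) <= 1e-15))
})

test_that("a single-frame trajectory equals the frame solver", {
  chain <- test_chain()
  q0 <- guard_posture(chain)
  meas <- project_markers(chain, forward_kinematics(chain, q0))
  one <- marker_trajectories(meas, rate = 300)
  sol <- solve_trajectory(chain, one, q_init = static_posture(chain))
  frame <- solve_frame(chain, meas, q_init = static_posture(chain))
  expect_equal(sol$q_traj$q[1, ], frame$q, tolerance = 1e-9)
})

test_that("time reversal reverses the solution on noise-free data", {
  chain <- test_chain()
  truth <- generate_q_trajectory(chain, short_script(peak = 4), rate = 100,
                                 seed = 4)
  markers <- render_markers(chain, truth)
  rev_markers <- marker_trajectories(
    markers$pos[rev(seq_len(n_frames(markers))), , , drop = FALSE],
    markers$rate)
  a <- solve_trajectory(chain, markers, q_init = guard_posture(chain))
  b <- solve_trajectory(chain, rev_markers, q_init = guard_posture(chain))
  expect_lt(max(abs(b$q_traj$q[rev(seq_len(nrow(b$q_traj$q))), ] -
                      a$q_traj$q)), 1e-5)
})

test_that("gap frames are flagged invalid, never interpolated", {
  chain <- test_chain()
  truth <- generate_q_trajectory(chain, short_script(peak = 4,
                                                     guard = 0.2, dpp = 0.3),
                                 rate = 60, seed = 5)
  markers <- render_markers(chain, truth)
  markers$pos[5:7, , ] <- NA  # full dropout
  sol <- suppressWarnings(
    solve_trajectory(chain, markers, q_init = guard_posture(chain)))
  expect_false(any(sol$q_traj$valid[5:7]))
  expect_true(all(is.na(sol$q_traj$q[5:7, ])))
  expect_true(all(sol$q_traj$valid[-(5:7)]))
})

test_that("the solution is invariant to a rigid transform of the scene", {
  chain <- test_chain()
  set.seed(27)
  q_star <- guard_posture(chain)
  q_star[7:24] <- q_star[7:24] + stats::runif(18, -0.2, 0.2)
  meas <- project_markers(chain, forward_kinematics(chain, q_star))
  Tg <- pose(cardan_to_matrix(c(0.4, -0.2, 0.3)), c(0.5, 0.1, -0.4))
  meas_t <- pose_apply(Tg, meas)
  rownames(meas_t) <- rownames(meas)
  fit <- solve_frame(chain, meas_t, q_init = guard_posture(chain))
  # joint angles unchanged; root pose composed with the transform
  expect_equal(unname(fit$q[7:24]), unname(q_star[7:24]), tolerance = 1e-8)
  root <- pose_compose(Tg, forward_kinematics(chain, q_star)$thorax)
  expect_equal(unname(fit$q[1:3]), root$t, tolerance = 1e-8)
  expect_equal(cardan_to_matrix(fit$q[4:6]), root$R, tolerance = 1e-8)
})

test_that("weight tuning selects the scheme that down-weights noisy markers", {
  chain <- test_chain()
  truth <- generate_q_trajectory(chain, short_script(peak = 3, guard = 0.2,
                                                     dpp = 0.4),
                                 rate = 30, seed = 6)
  markers <- render_markers(chain, truth)
  expect_error(tune_weights(chain, markers, list()), "at least one")
  uniform <- stats::setNames(rep(1, 21), names(default_weights(chain)))
  heavy <- default_weights(chain)
  # noise-free: all candidates tie at ~0; the first is returned
  tied <- tune_weights(chain, markers, list(a = uniform, b = heavy))
  expect_equal(as.numeric(tied), as.numeric(uniform))
  # hand-only noise: the thorax-heavy scheme (hand weight 1/10th) wins
  noisy <- markers
  set.seed(8)
  hand_idx <- which(marker_labels(markers) %in% c("LHND", "RHND"))
  noisy$pos[, hand_idx, ] <- noisy$pos[, hand_idx, ] +
    array(stats::rnorm(length(noisy$pos[, hand_idx, ]), 0, 0.01),
          dim(noisy$pos[, hand_idx, , drop = FALSE]))
  won <- tune_weights(chain, noisy, list(uniform = uniform, heavy = heavy))
  expect_equal(as.numeric(won), as.numeric(heavy))
})

test_that("exported pose streams reproduce the trajectory", {
  chain <- test_chain()
  q0 <- q_zero(chain)
  qt <- q_trajectory(rbind(q0, q0), rate = 60)
  stream <- export_poses(chain, qt)
  expect_equal(n_frames(stream), 2L)
  expect_equal(stream$T[1:3, 1:3, "thorax", 1], diag(3))
  # cardan re-extraction recovers joint angles
  set.seed(29)
  qs <- guard_posture(chain)
  qs[7:24] <- qs[7:24] + stats::runif(18, -0.3, 0.3)
  st2 <- export_poses(chain, q_trajectory(rbind(qs), rate = 60))
  sh <- cardan_angles(st2$T[1:3, 1:3, "clavicle_R", 1],
                      st2$T[1:3, 1:3, "upper_arm_R", 1])
  expect_equal(sh[1], qs[q_index(chain, "shoulder_R", "flex_ext")],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("planar two-link reduction matches closed-form inverse kinematics", {
  chain <- test_chain()
  l1 <- chain$lengths[["upper_arm"]]
  l2 <- chain$lengths[["forearm"]]
  free <- rep(FALSE, chain$n_q)
  free[q_index(chain, "shoulder_R", "flex_ext")] <- TRUE
  free[q_index(chain, "elbow_R", "flex_ext")] <- TRUE
  arm_markers <- c("RUAM", "RLEP", "RMEP", "RFAM", "RRSP", "RUSP", "RHND")
  set.seed(33)
  worst <- 0
  for (k in 1:100) {
    q_star <- q_zero(chain)
    ts <- stats::runif(1, -0.8, 1.2)
    te <- stats::runif(1, 0.2, 2.2)
    q_star[q_index(chain, "shoulder_R", "flex_ext")] <- ts
    q_star[q_index(chain, "elbow_R", "flex_ext")] <- te
    poses <- forward_kinematics(chain, q_star)
    meas <- project_markers(chain, poses)[arm_markers, ]
    # independent oracle from the wrist position
    shoulder <- joint_centers(poses, chain)$shoulder_R
    wrist <- joint_centers(poses, chain)$wrist_R
    oracle <- two_link_ik(wrist[1:2], shoulder[1:2], l1, l2)
    q_init <- q_zero(chain)
    q_init[free] <- c(0.3, 0.9)
    fit <- solve_frame(chain, meas, q_init = q_init, free = free)
    got <- c(fit$q[q_index(chain, "shoulder_R", "flex_ext")],
             fit$q[q_index(chain, "elbow_R", "flex_ext")])
    worst <- max(worst, max(abs(got - oracle)), max(abs(got - c(ts, te))))
  }
  expect_lt(worst, 1e-9)
})

test_that("joint-angle error grows monotonically with marker noise", {
  chain <- test_chain()
  truth <- generate_q_trajectory(chain, short_script(peak = 4, guard = 0.2,
                                                     dpp = 0.4),
                                 rate = 60, seed = 41)
  clean <- render_markers(chain, truth)
  rmse_at <- function(sd, seed) {
    mdl <- corruption_model(sta_amplitude = 0, sta_amplitude_thorax = 0,
                            placement_offset_sd = 0, jitter_sd = sd,
                            seed = seed)
    noisy <- corrupt_markers(clean, mdl)
    sol <- solve_trajectory(chain, noisy, q_init = guard_posture(chain))
    sqrt(mean((sol$q_traj$q[, 7:24] - truth$q[, 7:24])^2))
  }
  rmse <- vapply(c(0, 0.001, 0.002), function(s) rmse_at(s, 7), numeric(1))
  expect_true(all(diff(rmse) > 0))
})
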