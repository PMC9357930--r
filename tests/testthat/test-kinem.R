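test_that("joint-angle extraction masks locked axes and mirrors sides", {
  chain <- test_chain()
  # symmetric configuration in the flexion/abduction/internal convention
  q <- q_zero(chain)
  for (side in c("L", "R")) {
    sgn_ab <- if (side == "L") 1 else -1
    sgn_ir <- if (side == "L") -1 else 1
    q[q_index(chain, paste0("shoulder_", side), "flex_ext")] <- 0.5
    q[q_index(chain, paste0("shoulder_", side), "abd_add")] <- 0.3 * sgn_ab
    q[q_index(chain, paste0("shoulder_", side), "int_ext")] <- 0.2 * sgn_ir
    q[q_index(chain, paste0("elbow_", side), "flex_ext")] <- 1.1
  }
  stream <- export_poses(chain, q_trajectory(rbind(q), rate = 60))
  ang <- joint_angles(stream)
  # both sides report identical values under the mirrored convention
  for (jt in c("shoulder", "elbow")) {
    for (ax in c("flex_ext", "abd_add", "int_ext")) {
      v <- ang$value_deg[ang$joint == jt & ang$axis == ax]
      if (all(is.na(v))) next
      expect_equal(v[1], v[2], tolerance = 1e-9)
    }
  }
  sh_ab <- ang$value_deg[ang$joint == "shoulder" & ang$axis == "abd_add"]
  expect_equal(sh_ab, rep(0.3 * 180 / pi, 2), tolerance = 1e-9)
  # locked axes reported as NA with valid = FALSE
  expect_true(all(is.na(ang$value_deg[ang$joint == "elbow" &
                                        ang$axis == "abd_add"])))
  expect_true(all(is.na(ang$value_deg[ang$joint == "wrist" &
                                        ang$axis == "int_ext"])))
  expect_false(any(ang$valid[ang$joint == "elbow" & ang$axis == "abd_add"]))
})

test_that("joint-center distances are symmetric, equivariant, and need alignment", {
  chain <- test_chain()
  truth <- generate_q_trajectory(chain, short_script(peak = 3, guard = 0.2),
                                 rate = 60, seed = 13)
  a <- export_poses(chain, truth)
  d0 <- joint_center_distance(a, a, chain)
  expect_true(all(d0$distance_m < 1e-12))
  # a rigid offset of one whole stream appears as a constant |d|
  b <- a
  off <- c(0.01, -0.02, 0.02)
  b$T[1:3, 4, , ] <- b$T[1:3, 4, , ] + off
  dab <- joint_center_distance(a, b, chain)
  expect_equal(dab$distance_m, rep(sqrt(sum(off^2)), nrow(dab)),
               tolerance = 1e-12)
  # symmetry in the two streams
  dba <- joint_center_distance(b, a, chain)
  expect_equal(dab$distance_m, dba$distance_m)
  short <- pose_stream(a$T[, , , 1:3, drop = FALSE], a$rate)
  expect_error(joint_center_distance(a, short, chain), "resample_align")
})

test_that("center-of-mass speeds match analytic motions", {
  chain <- test_chain()
  n <- 100
  q <- matrix(0, n, chain$n_q, dimnames = list(NULL, chain$q_names))
  static <- export_poses(chain, q_trajectory(q, rate = 100))
  expect_true(all(com_speed(static, chain)$speed_mps < 1e-12))
  # uniform translation at |v|
  v <- c(1.2, -0.5, 0.3)
  q2 <- q
  tt <- (seq_len(n) - 1) / 100
  q2[, 1:3] <- outer(tt, v)
  uni <- com_speed(export_poses(chain, q_trajectory(q2, rate = 100)), chain)
  interior <- uni$frame > 1 & uni$frame < n
  expect_equal(uni$speed_mps[interior],
               rep(sqrt(sum(v^2)), sum(interior)), tolerance = 1e-9)
  # circular motion of radius r at angular rate w: speed = w * r + O(dt^2)
  r <- 0.5; w <- 6
  q3 <- q
  q3[, 1] <- r * cos(w * tt); q3[, 2] <- r * sin(w * tt)
  circ <- com_speed(export_poses(chain, q_trajectory(q3, rate = 100)), chain,
                    segments = "thorax")
  dt <- 1 / 100
  bound <- w * r * (w * dt)^2 / 6 * 1.5 + 1e-12
  err <- abs(circ$speed_mps[circ$frame > 1 & circ$frame < n] - w * r)
  expect_lt(max(err), bound)
  expect_error(com_speed(pose_stream(static$T[, , , 1:2, drop = FALSE], 100),
                         chain), "3 frames")
})

test_that("the zero-phase Butterworth honors its frequency contract", {
  fs <- 60
  tt <- seq(0, 20, by = 1 / fs)
  # unit DC gain
  const <- rep(2.5, length(tt))
  expect_equal(butterworth(const, fs), const, tolerance = 1e-9)
  # -6 dB (amplitude 0.5) at the cutoff for the dual-pass 4th-order filter
  x8 <- sin(2 * pi * 8 * tt)
  y8 <- butterworth(x8, fs)
  core <- seq(5 * fs, 15 * fs)  # avoid edges
  ratio <- max(abs(y8[core])) / 1
  expect_gt(ratio, 0.48); expect_lt(ratio, 0.52)
  # zero phase: a symmetric pulse keeps its peak sample
  pulse <- exp(-((tt - 10)^2) / 0.5)
  yp <- butterworth(pulse, fs)
  expect_equal(which.max(yp), which.max(pulse))
  # pass-band signals survive almost untouched
  x1 <- sin(2 * pi * 1 * tt)
  expect_lt(max(abs(butterworth(x1, fs)[core] - x1[core])), 0.01)
})

test_that("filtering handles gaps piecewise and rejects bad input", {
  fs <- 60
  x <- sin(2 * pi * 1 * seq(0, 10, by = 1 / fs))
  x[100:110] <- NA
  y <- suppressWarnings(butterworth(x, fs))
  expect_true(all(is.na(y[100:110])))
  expect_false(anyNA(y[-(100:110)]))
  expect_error(butterworth(x, fs, filter_spec(cutoff = 40)), "Nyquist")
  expect_error(butterworth(stats::rnorm(10), fs), "shorter")
})

test_that("resampling preserves pass-band content and degenerates gracefully", {
  fs <- 300
  tt <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 1 * tt)
  out <- resample_align(x, fs, 60)
  expect_equal(stats::median(diff(out$time)), 1 / 60, tolerance = 1e-12)
  core <- out$time > 2 & out$time < 8
  expect_lt(max(abs(out$x[core] - sin(2 * pi * out$time[core]))), 0.01)
  # identical rates: identity
  idem <- resample_align(x, fs, fs)
  expect_identical(idem$x, x)
  # constants stay constant
  cst <- resample_align(rep(3, length(tt)), fs, 60)
  expect_equal(cst$x, rep(3, length(cst$x)), tolerance = 1e-9)
  expect_error(resample_align(x, 300, 60, target_time = c(-5, 0)), "outside")
  expect_error(resample_align(x, 60, 300), "upsample")
})

test_that("filtering and differentiating nearly commute on punch motion", {
  chain <- test_chain()
  truth <- generate_q_trajectory(chain, short_script(peak = 4, dpp = 0.6,
                                                     guard = 0.4),
                                 rate = 60, seed = 14)
  stream <- export_poses(chain, truth)
  com <- c(chain$segments$hand_L$com, 1)
  p <- t(vapply(seq_len(n_frames(stream)),
                function(f) as.numeric(stream$T[1:3, , "hand_L", f] %*% com),
                numeric(3)))
  diff_then_filter <- vapply(1:3, function(k) {
    v <- c(NA, (p[-(1:2), k] - p[1:(nrow(p) - 2), k]) * 30, NA)
    butterworth(v, 60)
  }, numeric(nrow(p)))
  filter_then_diff <- vapply(1:3, function(k) {
    pf <- butterworth(p[, k], 60)
    c(NA, (pf[-(1:2)] - pf[1:(length(pf) - 2)]) * 30, NA)
  }, numeric(nrow(p)))
  keep <- stats::complete.cases(diff_then_filter, filter_then_diff)
  rms <- function(m) sqrt(mean(m^2))
  expect_lt(rms(diff_then_filter[keep, ] - filter_then_diff[keep, ]) /
              rms(filter_then_diff[keep, ]), 0.01)
})

test_that("the default filter preserves peak speeds of moderate punches", {
  chain <- test_chain()
  truth <- generate_q_trajectory(chain, short_script(peak = 4, dpp = 0.7,
                                                     guard = 0.5),
                                 rate = 60, seed = 15)
  stream <- export_poses(chain, truth)
  spd <- com_speed(stream, chain, segments = "hand_L")
  raw <- spd$speed_mps
  filt <- butterworth(raw, 60)
  expect_lt(abs(max(filt, na.rm = TRUE) - max(raw, na.rm = TRUE)) /
              max(raw, na.rm = TRUE), 0.02)
})
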