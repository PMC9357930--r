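test_that("the chain has the mandated topology and degree-of-freedom budget", {
  chain <- test_chain()
  expect_equal(chain$n_q, 24L)
  expect_setequal(chain$joints$ground_thorax$free_rotations,
                  c("flex_ext", "abd_add", "int_ext"))
  expect_setequal(chain$joints$ground_thorax$free_translations,
                  c("x", "y", "z"))
  for (side in c("L", "R")) {
    expect_length(chain$joints[[paste0("sternoclavicular_", side)]]$free_rotations, 2L)
    expect_setequal(chain$joints[[paste0("shoulder_", side)]]$free_rotations,
                    c("flex_ext", "abd_add", "int_ext"))
    expect_setequal(chain$joints[[paste0("elbow_", side)]]$free_rotations,
                    c("flex_ext", "int_ext"))   # abd/add locked
    expect_setequal(chain$joints[[paste0("wrist_", side)]]$free_rotations,
                    c("flex_ext", "abd_add"))   # int/ext locked
  }
  expect_length(chain$markers, 21L)
  # every marker attaches to exactly one known segment
  expect_true(all(vapply(chain$markers, function(m)
    m$segment %in% names(chain$segments), logical(1))))
})

test_that("chain construction is deterministic and validates the profile", {
  a <- build_chain(anthro_profile("female", 1.63, 59))
  b <- build_chain(anthro_profile("female", 1.63, 59))
  expect_identical(a, b)
  expect_error(anthro_profile("other", 1.7, 60), "unknown sex")
  expect_error(anthro_profile("male", -1, 60))
  expect_error(build_chain(anthro_profile("male", 1.8, 70),
                           overrides = list(femur = 0.4)), "unknown segment")
  c2 <- build_chain(anthro_profile("male", 1.8, 70),
                    overrides = list(upper_arm = 0.40))
  expect_equal(c2$lengths[["upper_arm"]], 0.40)
})

test_that("forward kinematics respects the template, rigid shifts and q length", {
  chain <- test_chain()
  poses <- forward_kinematics(chain, q_zero(chain))
  expect_equal(poses$thorax$R, diag(3))
  expect_equal(poses$thorax$t, c(0, 0, 0))
  # template poses reproduce the stored joint-center geometry
  jc <- joint_centers(poses, chain)
  expect_equal(jc$shoulder_R,
               poses$clavicle_R$t + chain$joint_local$shoulder_R$point)
  # rigid root shift moves every segment by exactly delta
  q <- q_zero(chain); delta <- c(0.3, -0.2, 0.55)
  q[1:3] <- delta
  poses2 <- forward_kinematics(chain, q)
  for (s in names(poses))
    expect_equal(poses2[[s]]$t, poses[[s]]$t + delta, tolerance = 1e-12)
  expect_error(forward_kinematics(chain, numeric(10)), "length")
})

test_that("relative rotations re-decompose to the joint angles (round trip)", {
  chain <- test_chain()
  set.seed(77)
  for (rep in 1:20) {
    q <- q_zero(chain)
    q[7:24] <- stats::runif(18, -1.0, 1.0)
    q[4:6] <- stats::runif(3, -0.5, 0.5)
    poses <- forward_kinematics(chain, q)
    for (side in c("L", "R")) {
      sh <- cardan_angles(poses[[paste0("clavicle_", side)]],
                          poses[[paste0("upper_arm_", side)]])
      expect_equal(sh[1], q[q_index(chain, paste0("shoulder_", side), "flex_ext")],
                   tolerance = 1e-10, ignore_attr = TRUE)
      expect_equal(sh[2], q[q_index(chain, paste0("shoulder_", side), "abd_add")],
                   tolerance = 1e-10, ignore_attr = TRUE)
      expect_equal(sh[3], q[q_index(chain, paste0("shoulder_", side), "int_ext")],
                   tolerance = 1e-10, ignore_attr = TRUE)
      el <- cardan_angles(poses[[paste0("upper_arm_", side)]],
                          poses[[paste0("forearm_", side)]])
      expect_equal(el[2], 0, tolerance = 1e-10, ignore_attr = TRUE)  # locked
      wr <- cardan_angles(poses[[paste0("forearm_", side)]],
                          poses[[paste0("hand_", side)]])
      expect_equal(wr[3], 0, tolerance = 1e-10, ignore_attr = TRUE)  # locked
    }
  }
})

test_that("forward kinematics preserves inter-joint-center distances", {
  chain <- test_chain()
  jc0 <- joint_centers(forward_kinematics(chain, q_zero(chain)), chain)
  d0 <- function(jc) c(
    sqrt(sum((jc$shoulder_R - jc$elbow_R)^2)),
    sqrt(sum((jc$elbow_R - jc$wrist_R)^2)),
    sqrt(sum((jc$shoulder_L - jc$elbow_L)^2)),
    sqrt(sum((jc$cervical - jc$thoracic)^2)))
  set.seed(9)
  for (rep in 1:10) {
    q <- q_zero(chain)
    q[1:6] <- stats::runif(6, -0.5, 0.5)
    q[7:24] <- stats::runif(18, -1.2, 1.2)
    jc <- joint_centers(forward_kinematics(chain, q), chain)
    expect_equal(d0(jc), d0(jc0), tolerance = 1e-10)
  }
})

test_that("joint centers are equivariant and elbow sits at the epicondyle midpoint", {
  chain <- test_chain()
  q <- guard_posture(chain)
  poses <- forward_kinematics(chain, q)
  jc <- joint_centers(poses, chain)
  mk <- project_markers(chain, poses)
  expect_equal(as.numeric((mk["RLEP", ] + mk["RMEP", ]) / 2), jc$elbow_R,
               tolerance = 1e-12)
  expect_equal(as.numeric((mk["LRSP", ] + mk["LUSP", ]) / 2), jc$wrist_L,
               tolerance = 1e-12)
  # global rigid transform applied at the root transforms all centers
  set.seed(12)
  Tg <- pose(random_rotation(), stats::rnorm(3))
  root <- pose_compose(Tg, poses$thorax)
  q2 <- q
  q2[1:3] <- root$t
  q2[4:6] <- as.numeric(cardan_angles(root$R))
  jc2 <- joint_centers(forward_kinematics(chain, q2), chain)
  for (j in names(jc))
    expect_equal(jc2[[j]], pose_apply(Tg, jc[[j]]), tolerance = 1e-9)
  expect_error(joint_centers(poses["thorax"], chain), "shoulder_L")
})

test_that("marker projection maps locals through segment poses", {
  chain <- test_chain()
  poses <- forward_kinematics(chain, q_zero(chain))
  mk <- project_markers(chain, poses)
  # thorax poses are the identity at q = 0, so thorax markers equal locals
  expect_equal(as.numeric(mk["C7", ]), chain$markers$C7$local)
  # rotating only the hand moves only hand markers
  q <- q_zero(chain)
  q[q_index(chain, "wrist_R", "flex_ext")] <- 0.6
  mk2 <- project_markers(chain, forward_kinematics(chain, q))
  moved <- rowSums(abs(mk2 - mk)) > 1e-12
  expect_true(moved[["RHND"]])
  expect_false(any(moved[setdiff(names(moved), "RHND")]))
  expect_error(project_markers(chain, poses["thorax"]), "missing segment")
})

test_that("all poses satisfy rotation invariants after arbitrary configurations", {
  chain <- test_chain()
  set.seed(31)
  q <- q_zero(chain)
  q[4:24] <- stats::runif(21, -1.5, 1.5)
  for (p in forward_kinematics(chain, q))
    expect_true(is_rotation(p$R, 1e-9))
})

test_that("template scaling is a fixed point and tracks landmark ratios", {
  chain <- test_chain()
  q0 <- static_posture(chain)
  static <- marker_trajectories(
    project_markers(chain, forward_kinematics(chain, q0)), rate = 300)
  rescaled <- scale_template(chain, static)
  expect_equal(rescaled$lengths, chain$lengths, tolerance = 1e-9)
  for (m in names(chain$markers))
    expect_equal(rescaled$markers[[m]]$local, chain$markers[[m]]$local,
                 tolerance = 1e-7)

  # landmarks 10% farther apart scale the segment lengths by exactly 1.10
  static2 <- marker_trajectories(static$pos[1, , ] * 1.10, rate = 300)
  scaled2 <- scale_template(chain, static2)
  expect_equal(unname(scaled2$lengths), unname(chain$lengths * 1.10),
               tolerance = 1e-9)

  # a subject whose upper arm alone is longer is recovered approximately
  # (non-axial landmark offsets do not scale with the bone)
  longer <- build_chain(chain$profile,
                        overrides = list(upper_arm = chain$lengths[["upper_arm"]] * 1.10))
  static3 <- marker_trajectories(
    project_markers(longer, forward_kinematics(longer, q0)), rate = 300)
  scaled3 <- scale_template(chain, static3)
  expect_equal(scaled3$lengths[["upper_arm"]],
               chain$lengths[["upper_arm"]] * 1.10, tolerance = 0.01)

  # missing landmarks and empty frames are rejected
  partial <- static
  partial$pos <- partial$pos[, setdiff(marker_labels(static), "C7"), ,
                             drop = FALSE]
  expect_error(scale_template(chain, partial), "C7")
})
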