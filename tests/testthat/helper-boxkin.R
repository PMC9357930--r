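# Shared fixtures. The tall-male chain mirrors one of the athlete profiles;
# building it once keeps the suite fast.
test_chain <- local({
  chain <- NULL
  function() {
    if (is.null(chain)) chain <<- build_chain(anthro_profile("male", 1.90, 78))
    chain
  }
})

# A short, cheap trial script (one lead-arm direct punch).
short_script <- function(peak = 6, dpp = 0.4, guard = 0.3, reps = 1L)
  punch_script("direct_face", repetitions = reps, peak_hand_speed = peak,
               duration_per_punch = dpp, guard_hold = guard)

# Random proper rotation, uniform-ish (QR of a Gaussian matrix, det fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Independent closed-form two-link planar inverse kinematics (shoulder
# flexion + elbow flexion about Z, links hanging along -Y at zero), used as
# the oracle for the planar MKO reduction. Returns c(theta_s, theta_e) with
# the elbow-positive branch.
two_link_ik <- function(wrist, shoulder, l1, l2) {
  d <- wrist - shoulder
  r2 <- d[1]^2 + d[2]^2
  ce <- (r2 - l1^2 - l2^2) / (2 * l1 * l2)
  ce <- max(-1, min(1, ce))
  te <- acos(ce)
  ts <- atan2(d[1], -d[2]) - atan2(l2 * sin(te), l1 + l2 * cos(te))
  c(ts, te)
}

# Hand center-of-mass peak speed computed independently of the generator's
# internals: forward kinematics frame by frame + central differences.
measured_hand_peak <- function(chain, q_traj) {
  nf <- n_frames(q_traj)
  pk <- 0
  for (hand in c("hand_L", "hand_R")) {
    com <- chain$segments[[hand]]$com
    p <- t(vapply(seq_len(nf), function(f) {
      fk <- forward_kinematics(chain, q_traj$q[f, ])[[hand]]
      pose_apply(fk, com)
    }, numeric(3)))
    v <- (p[3:nf, , drop = FALSE] - p[1:(nf - 2), , drop = FALSE]) *
      q_traj$rate / 2
    pk <- max(pk, sqrt(max(rowSums(v^2))))
  }
  pk
}

# Build the acceptance-style run configuration in code (no file I/O).
scenario_config <- function(chain_profile = list(sex = "male", height = 1.90,
                                                 mass = 78),
                            bias_deg = 2.4, elbow_offset_cm = c(1.79, 1.79, 1.79),
                            peak = 7.5, seed = 1, reps = 4L,
                            marker_rate = 300) {
  list(
    profile = do.call(anthro_profile, chain_profile),
    script = punch_script("direct_face", repetitions = reps,
                          peak_hand_speed = peak),
    corruption = corruption_model(placement_offset_sd = 0),
    emulation = system_emulation(
      angle_bias = c(shoulder_L.flex_ext = bias_deg * pi / 180),
      center_offset = list(elbow_L = elbow_offset_cm / 100),
      rate = 60),
    filter = filter_spec(),
    weights = NULL, cardan_sequence = "zxy", front_side = "L",
    marker_rate = marker_rate, seed = seed, out_dir = tempdir(),
    hash = "test")
}
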