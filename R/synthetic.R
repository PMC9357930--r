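# Run code with a local, restored RNG state so generators are reproducible
# under their seed without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed deterministically
#' @param seed parent integer seed.
#' @param offset small integer distinguishing the consumer.
#' @return integer below 2^31 - 1.
#' @export
derive_seed <- function(seed, offset = 0) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

#' Shadow-boxing trial script
#'
#' Describes one synthetic trial: the punch combination, which arm leads,
#' the number of repetitions, the target peak hand speed the generator
#' calibrates to, and timing. The five trial types mirror classical
#' shadow-boxing combinations: lead-arm direct punches to face or body, a
#' double direct, a rear jab followed by a lead hook, and an
#' uppercut-hook-hook combination.
#'
#' @param punch_type one of `direct_face`, `direct_body`, `double_direct`,
#'   `jab_hook`, `uppercut_hook_hook`.
#' @param side which physical arm is the lead (front) arm: `"L"` (orthodox,
#'   default) or `"R"` (southpaw).
#' @param repetitions number of repetitions of the combination (>= 1).
#' @param peak_hand_speed target peak hand center-of-mass speed, m/s
#'   (default 7.5, a typical elite lead-hand punch peak).
#' @param duration_per_punch duration of one punch (extension plus
#'   retraction), s.
#' @param guard_hold guard/footwork hold between repetitions, s.
#' @return object of class `punch_script`.
#' @export
punch_script <- function(punch_type = c("direct_face", "direct_body",
                                        "double_direct", "jab_hook",
                                        "uppercut_hook_hook"),
                         side = "L", repetitions = 4L,
                         peak_hand_speed = 7.5, duration_per_punch = 0.4,
                         guard_hold = 0.8) {
  punch_type <- match.arg(punch_type)
  stopifnot(side %in% c("L", "R"), repetitions >= 1,
            peak_hand_speed >= 0, duration_per_punch > 0, guard_hold > 0)
  structure(list(punch_type = punch_type, side = side,
                 repetitions = as.integer(repetitions),
                 peak_hand_speed = peak_hand_speed,
                 duration_per_punch = duration_per_punch,
                 guard_hold = guard_hold),
            class = "punch_script")
}

#' @export
print.punch_script <- function(x, ...) {
  cat(sprintf("<punch_script> %s, front = %s, %d reps, target %.1f m/s\n",
              x$punch_type, x$side, x$repetitions, x$peak_hand_speed))
  invisible(x)
}

#' Guard posture
#'
#' Defensive posture with both elbows flexed, hands guarding body and face:
#' the resting configuration between punches.
#'
#' @param chain a [build_chain()] result.
#' @return named q vector.
#' @export
guard_posture <- function(chain) {
  q <- q_zero(chain)
  set_conv <- function(joint, axis, value_conv, side) {
    # value given in the flexion/abduction/internal-positive convention
    q[q_index(chain, paste0(joint, "_", side), axis)] <<-
      value_conv * .axis_sign(axis, side)
  }
  for (side in c("L", "R")) {
    set_conv("sternoclavicular", "abd_add", 0.08, side)   # slight elevation
    set_conv("sternoclavicular", "int_ext", -0.12, side)  # protraction
    set_conv("shoulder", "flex_ext", 0.70, side)
    set_conv("shoulder", "abd_add", -0.10, side)          # slight adduction
    set_conv("shoulder", "int_ext", 0.30, side)
    set_conv("elbow", "flex_ext", 1.90, side)
    set_conv("elbow", "int_ext", 0.20, side)
  }
  q
}

# Punch archetypes: target postures of the punching arm (in the
# flexion/abduction/internal-positive convention, radians) plus root motion
# (lunge along X in m, yaw toward the target in rad, vertical drop in m).
.punch_archetypes <- list(
  direct = list(shoulder.flex_ext = 1.50, shoulder.abd_add = 0.10,
                shoulder.int_ext = 0.10, elbow.flex_ext = 0.15,
                elbow.int_ext = 0.40, wrist.flex_ext = 0,
                lunge = 0.15, yaw = 0.45, drop = 0),
  direct_low = list(shoulder.flex_ext = 1.10, shoulder.abd_add = 0.10,
                    shoulder.int_ext = 0.10, elbow.flex_ext = 0.25,
                    elbow.int_ext = 0.40, wrist.flex_ext = 0,
                    lunge = 0.15, yaw = 0.45, drop = -0.06),
  hook = list(shoulder.flex_ext = 1.10, shoulder.abd_add = 1.10,
              shoulder.int_ext = 0.50, elbow.flex_ext = 1.40,
              elbow.int_ext = 0.20, wrist.flex_ext = 0,
              lunge = 0.05, yaw = 0.50, drop = 0),
  uppercut = list(shoulder.flex_ext = 0.90, shoulder.abd_add = 0.15,
                  shoulder.int_ext = -0.30, elbow.flex_ext = 1.50,
                  elbow.int_ext = -0.40, wrist.flex_ext = 0,
                  lunge = 0.05, yaw = 0.30, drop = -0.05)
)

# Stroke sequences per trial type; arm is "front" or "rear".
.punch_sequences <- list(
  direct_face = list(list(arch = "direct", arm = "front")),
  direct_body = list(list(arch = "direct_low", arm = "front")),
  double_direct = list(list(arch = "direct", arm = "front"),
                       list(arch = "direct", arm = "front")),
  jab_hook = list(list(arch = "direct", arm = "rear"),
                  list(arch = "hook", arm = "front")),
  uppercut_hook_hook = list(list(arch = "uppercut", arm = "front"),
                            list(arch = "hook", arm = "front"),
                            list(arch = "hook", arm = "front"))
)

# Target posture for one stroke at amplitude alpha, starting from guard.
.stroke_target <- function(chain, guard, stroke, front_side, alpha) {
  arch <- .punch_archetypes[[stroke$arch]]
  side <- if (stroke$arm == "front") front_side else setdiff(c("L", "R"),
                                                             front_side)
  q <- guard
  for (nm in names(arch)) {
    if (nm %in% c("lunge", "yaw", "drop")) next
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- q_index(chain, paste0(parts[1], "_", side), parts[2])
    target_raw <- arch[[nm]] * .axis_sign(parts[2], side)
    q[i] <- guard[i] + alpha * (target_raw - guard[i])
  }
  yaw_sign <- if (side == "R") 1 else -1  # rotate torso into the punch
  q[q_index(chain, "root", "tx")] <- guard[["root.tx"]] + alpha * arch$lunge
  q[q_index(chain, "root", "ty")] <- guard[["root.ty"]] + alpha * arch$drop
  q[q_index(chain, "root", "rz")] <- guard[["root.rz"]]
  q[q_index(chain, "root", "ry")] <- guard[["root.ry"]] +
    alpha * yaw_sign * arch$yaw
  q
}

# Minimum-jerk interpolant: C2, zero velocity/acceleration at both ends.
.minjerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# Keyframe schedule for a script: times and postures, min-jerk interpolated.
.keyframes <- function(chain, script, alpha) {
  guard <- guard_posture(chain)
  seqs <- .punch_sequences[[script$punch_type]]
  times <- 0
  postures <- list(guard)
  t <- script$guard_hold
  times <- c(times, t); postures <- c(postures, list(guard))
  # Punch extension is faster than retraction (an elite jab extends in
  # roughly 100-150 ms): 35% of the punch duration out, 65% back.
  t_out <- 0.35 * script$duration_per_punch
  t_back <- 0.65 * script$duration_per_punch
  for (rep in seq_len(script$repetitions)) {
    for (stroke in seqs) {
      tgt <- .stroke_target(chain, guard, stroke, script$side, alpha)
      t <- t + t_out
      times <- c(times, t); postures <- c(postures, list(tgt))
      t <- t + t_back
      times <- c(times, t); postures <- c(postures, list(guard))
    }
    t <- t + script$guard_hold
    times <- c(times, t); postures <- c(postures, list(guard))
  }
  list(times = times, postures = do.call(rbind, postures))
}

.sample_keyframes <- function(kf, tt) {
  n_q <- ncol(kf$postures)
  qmat <- matrix(NA_real_, length(tt), n_q)
  seg_idx <- findInterval(tt, kf$times, rightmost.closed = TRUE)
  seg_idx[seg_idx < 1L] <- 1L
  seg_idx[seg_idx >= length(kf$times)] <- length(kf$times) - 1L
  for (k in unique(seg_idx)) {
    sel <- seg_idx == k
    t0 <- kf$times[k]; t1 <- kf$times[k + 1]
    s <- .minjerk(pmin(1, pmax(0, (tt[sel] - t0) / (t1 - t0))))
    q0 <- kf$postures[k, ]; q1 <- kf$postures[k + 1, ]
    qmat[sel, ] <- outer(s, q1 - q0) + matrix(q0, sum(sel), length(q0),
                                              byrow = TRUE)
  }
  qmat
}

# Peak hand CoM speed of a q matrix at a given rate (both hands).
.peak_hand_speed <- function(chain, qmat, rate) {
  nf <- nrow(qmat)
  pk <- 0
  for (hand in c("hand_L", "hand_R")) {
    com <- chain$segments[[hand]]$com
    p <- matrix(NA_real_, nf, 3)
    for (f in seq_len(nf)) {
      fk <- .fk_fast(chain, qmat[f, ])[[hand]]
      p[f, ] <- as.numeric(fk$R %*% com) + fk$t
    }
    v <- (p[3:nf, , drop = FALSE] - p[1:(nf - 2), , drop = FALSE]) * rate / 2
    pk <- max(pk, sqrt(max(rowSums(v^2))))
  }
  pk
}

# Largest admissible punch amplitude before any coordinate hits its bound.
.alpha_max <- function(chain, script) {
  guard <- guard_posture(chain)
  bounds <- .q_bounds(chain)
  amax <- 4
  for (stroke in .punch_sequences[[script$punch_type]]) {
    tgt <- .stroke_target(chain, guard, stroke, script$side, 1)
    delta <- tgt - guard
    for (i in which(abs(delta) > 1e-12)) {
      room <- if (delta[i] > 0) bounds$upper[i] - guard[i] else
        guard[i] - bounds$lower[i]
      amax <- min(amax, room / abs(delta[i]))
    }
  }
  amax
}

#' Generate a ground-truth boxing q-trajectory
#'
#' Builds smooth (C2) generalized-coordinate trajectories alternating guard
#' posture, footwork sway of the root, and minimum-jerk punch extensions
#' according to the script. Punch amplitudes are calibrated iteratively so
#' the peak hand center-of-mass speed matches `script$peak_hand_speed`
#' within 0.5% (well inside the 2% contract); an unreachable target raises
#' an error stating the attainable bound. Footwork is modeled as a low-level
#' root oscillation (peak speed well below punch speeds). All locked degrees
#' of freedom are respected by construction.
#'
#' @param chain a [build_chain()] result.
#' @param script a [punch_script()].
#' @param rate sampling rate in Hz (default 300).
#' @param seed integer seed controlling footwork phases.
#' @param amplitude optional fixed punch amplitude; `0` yields a guard-only
#'   trial (no punches, calibration skipped), `NULL` (default) calibrates to
#'   the target peak speed.
#' @return a [q_trajectory()] with attribute `"amplitude"` (the calibrated
#'   punch amplitude) and `"measured_peak_speed"` (m/s).
#' @export
generate_q_trajectory <- function(chain, script, rate = 300, seed = 1,
                                  amplitude = NULL) {
  stopifnot(inherits(script, "punch_script"), rate > 0)
  seqs <- .punch_sequences[[script$punch_type]]
  total <- script$guard_hold +
    script$repetitions *
      (length(seqs) * script$duration_per_punch + script$guard_hold)
  tt <- seq(0, total, by = 1 / rate)

  n_q <- chain$n_q
  sway <- .with_seed(seed, {
    list(
      # footwork: root translation oscillation (x, y, z), m and Hz
      ph = stats::runif(3, 0, 2 * pi),
      amp = c(0.030, 0.015, 0.030),
      frq = c(1.6, 3.2, 1.3),
      # postural sway: no joint is ever held perfectly still; small slow
      # oscillations (up to ~1.5 deg) on every free joint angle
      j_amp = stats::runif(n_q - 6L, 0.010, 0.025),
      j_frq = stats::runif(n_q - 6L, 0.6, 1.4),
      j_ph = stats::runif(n_q - 6L, 0, 2 * pi))
  })
  sway_mat <- vapply(1:3, function(k) {
    sway$amp[k] * sin(2 * pi * sway$frq[k] * tt + sway$ph[k])
  }, numeric(length(tt)))
  bounds <- .q_bounds(chain)

  build <- function(alpha) {
    kf <- .keyframes(chain, script, alpha)
    qmat <- .sample_keyframes(kf, tt)
    qmat[, 1:3] <- qmat[, 1:3] + sway_mat
    for (j in 7:n_q) {
      k <- j - 6L
      # keep the swayed trajectory strictly inside the coordinate bounds
      amp <- min(sway$j_amp[k],
                 0.8 * (min(qmat[, j]) - bounds$lower[j]),
                 0.8 * (bounds$upper[j] - max(qmat[, j])))
      if (amp <= 0) next
      qmat[, j] <- qmat[, j] +
        amp * sin(2 * pi * sway$j_frq[k] * tt + sway$j_ph[k])
    }
    colnames(qmat) <- chain$q_names
    qmat
  }

  if (!is.null(amplitude)) {
    alpha <- amplitude
  } else {
    target <- script$peak_hand_speed
    amax <- .alpha_max(chain, script)
    v_at <- function(a) .peak_hand_speed(chain, build(a), rate)
    v_max <- v_at(amax)
    if (v_max < target * 0.995)
      stop(sprintf(paste0("peak hand speed %.2f m/s unattainable for this ",
                          "script; attainable bound is %.2f m/s"),
                   target, v_max), call. = FALSE)
    a0 <- min(0.6, amax); v0 <- v_at(a0)
    a1 <- min(amax, max(0.05, a0 * target / max(v0, 1e-9)))
    for (it in 1:8) {
      v1 <- v_at(a1)
      if (abs(v1 - target) / target < 0.005) break
      slope <- (v1 - v0) / (a1 - a0)
      a_new <- a1 + (target - v1) / slope
      a0 <- a1; v0 <- v1
      a1 <- min(amax, max(1e-3, a_new))
    }
    alpha <- a1
  }
  qmat <- build(alpha)
  out <- q_trajectory(qmat, rate)
  attr(out, "amplitude") <- alpha
  attr(out, "measured_peak_speed") <- .peak_hand_speed(chain, qmat, rate)
  out
}

#' Render noise-free marker trajectories from a q-trajectory
#'
#' Frame-by-frame forward kinematics followed by marker projection, the
#' ideal optoelectronic measurement of the synthetic motion.
#'
#' @param chain a [build_chain()] result.
#' @param q_traj a [q_trajectory()].
#' @return a [marker_trajectories()] at the trajectory's rate.
#' @export
render_markers <- function(chain, q_traj) {
  stopifnot(inherits(q_traj, "q_trajectory"))
  nf <- n_frames(q_traj)
  labs <- rownames(chain$marker_local)
  pos <- array(NA_real_, c(nf, length(labs), 3),
               dimnames = list(NULL, labs, c("x", "y", "z")))
  for (f in seq_len(nf)) {
    poses <- .fk_fast(chain, q_traj$q[f, ])
    pos[f, , ] <- .project_fast(chain, poses)
  }
  marker_trajectories(pos, q_traj$rate, q_traj$start_time)
}

#' Marker corruption model
#'
#' Parameters of the synthetic skin-marker error: a constant per-marker
#' placement offset (isotropic Gaussian), a low-pass-filtered Gaussian
#' soft-tissue-artifact displacement with prescribed 3D RMS amplitude and
#' bandwidth (smaller on the thorax, whose markers ride on less mobile soft
#' tissue), and white measurement jitter. These magnitudes are stand-ins of
#' the right order for skin-marker error; they are reported in output
#' metadata, not asserted as a validated soft-tissue model.
#'
#' @param sta_amplitude 3D RMS soft-tissue displacement on arm segments, m.
#' @param sta_amplitude_thorax 3D RMS on thorax markers, m.
#' @param sta_bandwidth low-pass bandwidth of the artifact, Hz.
#' @param jitter_sd white jitter standard deviation per coordinate, m.
#' @param placement_offset_sd per-coordinate sd of the constant placement
#'   offset, m.
#' @param seed integer seed.
#' @return object of class `corruption_model`.
#' @export
corruption_model <- function(sta_amplitude = 0.010,
                             sta_amplitude_thorax = 0.005,
                             sta_bandwidth = 3, jitter_sd = 0.0005,
                             placement_offset_sd = 0.005, seed = 1) {
  stopifnot(sta_amplitude >= 0, sta_amplitude_thorax >= 0,
            sta_bandwidth >= 0, jitter_sd >= 0, placement_offset_sd >= 0)
  structure(list(sta_amplitude = sta_amplitude,
                 sta_amplitude_thorax = sta_amplitude_thorax,
                 sta_bandwidth = sta_bandwidth, jitter_sd = jitter_sd,
                 placement_offset_sd = placement_offset_sd,
                 seed = as.integer(seed)),
            class = "corruption_model")
}

#' Corrupt marker trajectories with placement, soft-tissue and jitter noise
#'
#' Adds, in order: (i) a constant per-marker placement offset drawn from an
#' isotropic Gaussian, (ii) a band-limited Gaussian soft-tissue-artifact
#' displacement rescaled to the prescribed 3D RMS amplitude, (iii) white
#' jitter. All terms are reproducible under the model's seed; zero
#' parameters leave the input bit-identical.
#'
#' @param markers a [marker_trajectories()].
#' @param model a [corruption_model()].
#' @param thorax_markers labels treated as thorax-mounted (default: markers
#'   named `SJN`, `SXS`, `C7`, `T8`, `T10`).
#' @return a corrupted [marker_trajectories()].
#' @export
corrupt_markers <- function(markers, model,
                            thorax_markers = c("SJN", "SXS", "C7", "T8",
                                               "T10")) {
  stopifnot(inherits(markers, "marker_trajectories"),
            inherits(model, "corruption_model"))
  pos <- markers$pos
  nf <- dim(pos)[1]; nm <- dim(pos)[2]
  labs <- marker_labels(markers)
  .with_seed(model$seed, {
    if (model$placement_offset_sd > 0) {
      off <- matrix(stats::rnorm(nm * 3, 0, model$placement_offset_sd), nm, 3)
      for (m in seq_len(nm))
        pos[, m, ] <- sweep(pos[, m, , drop = FALSE], 3, -off[m, ])[, 1, ]
    }
    sta_amp <- ifelse(labs %in% thorax_markers,
                      model$sta_amplitude_thorax, model$sta_amplitude)
    if (any(sta_amp > 0) && model$sta_bandwidth > 0 && nf > 12) {
      per_axis <- sta_amp / sqrt(3)
      # band-limit white noise, then rescale to the prescribed amplitude
      # (the rescaling makes edge transients immaterial)
      ba <- signal::butter(2, min(model$sta_bandwidth / (markers$rate / 2),
                                  0.99), type = "low")
      for (m in seq_len(nm)) {
        if (per_axis[m] == 0) next
        for (ax in 1:3) {
          z <- as.numeric(signal::filtfilt(ba, stats::rnorm(nf)))
          z <- z / stats::sd(z) * per_axis[m]
          pos[, m, ax] <- pos[, m, ax] + z
        }
      }
    }
    if (model$jitter_sd > 0)
      pos <- pos + array(stats::rnorm(length(pos), 0, model$jitter_sd),
                         dim(pos))
  })
  marker_trajectories(pos, markers$rate, markers$start_time)
}

#' Markerless-system emulation parameters
#'
#' Describes the second measurement stream: its (lower) sampling rate,
#' constant per-coordinate angle biases, optional constant joint-center
#' offsets (emulating inter-system differences in joint-center definition),
#' and Gaussian pose noise applied in coordinate space so that every output
#' pose remains a valid rigid transform.
#'
#' @param angle_bias named numeric vector of constant offsets (radians) on
#'   generalized coordinates, names among the chain's `q_names` (e.g.
#'   `"shoulder_L.flex_ext"`).
#' @param pose_noise_sd_rad Gaussian noise sd on rotational coordinates,
#'   radians.
#' @param pose_noise_sd_m Gaussian noise sd on root translation, m.
#' @param rate output sampling rate, Hz (default 60).
#' @param center_offset named list of global 3-vectors (m) displacing a
#'   joint's center, names among `shoulder_L`, `elbow_L`, `wrist_L` and the
#'   `_R` counterparts.
#' @return object of class `system_emulation`.
#' @export
system_emulation <- function(angle_bias = numeric(0), pose_noise_sd_rad = 0,
                             pose_noise_sd_m = 0, rate = 60,
                             center_offset = list()) {
  stopifnot(rate > 0, pose_noise_sd_rad >= 0, pose_noise_sd_m >= 0)
  if (length(angle_bias) && is.null(names(angle_bias)))
    stop("angle_bias must be a named vector of q coordinates", call. = FALSE)
  structure(list(angle_bias = angle_bias,
                 pose_noise_sd_rad = pose_noise_sd_rad,
                 pose_noise_sd_m = pose_noise_sd_m, rate = rate,
                 center_offset = center_offset),
            class = "system_emulation")
}

#' Emulate the markerless pose stream
#'
#' Resamples the ground-truth q-trajectory to the emulated system's rate
#' (linear interpolation of the smooth coordinates), injects the configured
#' constant angle biases and Gaussian pose noise in coordinate space, runs
#' forward kinematics, and finally applies any configured joint-center
#' offsets to the corresponding proximal-segment translations. Because noise
#' enters before the kinematics, every output pose satisfies the rigid-body
#' invariants exactly.
#'
#' @param chain a [build_chain()] result.
#' @param q_traj the ground-truth [q_trajectory()].
#' @param emu a [system_emulation()].
#' @param seed integer seed for the pose noise.
#' @return a [pose_stream()] at `emu$rate`.
#' @export
emulate_markerless <- function(chain, q_traj, emu, seed = 1) {
  stopifnot(inherits(q_traj, "q_trajectory"),
            inherits(emu, "system_emulation"))
  if (emu$rate > q_traj$rate + 1e-9)
    stop("emulated rate must not exceed the source rate", call. = FALSE)
  t_src <- time_axis(q_traj)
  t_out <- seq(t_src[1], t_src[length(t_src)], by = 1 / emu$rate)
  qr <- vapply(seq_len(ncol(q_traj$q)), function(j) {
    stats::approx(t_src, q_traj$q[, j], xout = t_out, rule = 1)$y
  }, numeric(length(t_out)))
  colnames(qr) <- colnames(q_traj$q)

  qb <- qr
  if (length(emu$angle_bias)) {
    bad <- setdiff(names(emu$angle_bias), chain$q_names)
    if (length(bad))
      stop("unknown coordinate(s) in angle_bias: ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(emu$angle_bias))
      qb[, nm] <- qb[, nm] + emu$angle_bias[[nm]]
  }
  trans_noise <- NULL
  if (emu$pose_noise_sd_rad > 0 || emu$pose_noise_sd_m > 0) {
    .with_seed(seed, {
      rot_cols <- setdiff(seq_len(ncol(qb)), 1:3)
      if (emu$pose_noise_sd_rad > 0)
        qb[, rot_cols] <- qb[, rot_cols] +
          matrix(stats::rnorm(length(rot_cols) * nrow(qb), 0,
                              emu$pose_noise_sd_rad),
                 ncol = length(rot_cols))
      if (emu$pose_noise_sd_m > 0)
        trans_noise <- matrix(
          stats::rnorm(3 * nrow(qb) * length(chain$segments), 0,
                       emu$pose_noise_sd_m),
          nrow = nrow(qb))
    })
  }

  # Segment orientations carry the biased/noisy coordinates; segment origins
  # (which ARE the exported joint centers) stay anchored to the observed,
  # unbiased kinematics — a markerless system estimates positions from image
  # evidence, so an orientation offset does not proportionally displace its
  # joint centers. Explicit center offsets then displace the corresponding
  # origin directly.
  nf <- nrow(qb)
  frames <- vector("list", nf)
  identical_q <- identical(qb, qr)
  for (f in seq_len(nf)) {
    fk_rot <- .fk_fast(chain, qb[f, ])
    if (identical_q) {
      frames[[f]] <- fk_rot
    } else {
      fk_pos <- .fk_fast(chain, qr[f, ])
      frames[[f]] <- Map(function(a, b) list(R = a$R, t = b$t),
                         fk_rot, fk_pos)
    }
  }
  stream <- .poses_to_stream(frames, names(chain$segments), emu$rate,
                             t_out[1])
  if (!is.null(trans_noise)) {
    for (s in seq_along(chain$segments))
      stream$T[1:3, 4, s, ] <- stream$T[1:3, 4, s, ] +
        t(trans_noise[, (3 * s - 2):(3 * s)])
  }
  if (length(emu$center_offset)) {
    for (jname in names(emu$center_offset)) {
      jl <- chain$joints[[jname]]
      if (is.null(jl))
        stop("unknown joint in center_offset: ", jname, call. = FALSE)
      d <- emu$center_offset[[jname]]
      # the joint's center is the origin of its distal (child) segment
      stream$T[1:3, 4, jl$segment, ] <- stream$T[1:3, 4, jl$segment, ] + d
    }
  }
  stream
}
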