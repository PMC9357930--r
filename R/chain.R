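#' Anthropometric profile
#'
#' Subject descriptors driving the scaling of the generic upper-body template:
#' sex selects the sex-specific table of segment-length and center-of-mass
#' fractions, stature scales segment lengths.
#'
#' @param sex `"female"` or `"male"`.
#' @param height stature in meters.
#' @param mass body mass in kilograms.
#' @return object of class `anthro_profile`.
#' @export
#' @examples
#' anthro_profile("male", 1.90, 78)
anthro_profile <- function(sex, height, mass) {
  sex <- as.character(sex)
  if (!sex %in% c("female", "male"))
    stop("unknown sex label '", sex, "': must be 'female' or 'male'",
         call. = FALSE)
  stopifnot(is.numeric(height), length(height) == 1L, is.finite(height),
            height > 0, is.numeric(mass), length(mass) == 1L,
            is.finite(mass), mass > 0)
  structure(list(sex = sex, height = height, mass = mass),
            class = "anthro_profile")
}

#' @export
print.anthro_profile <- function(x, ...) {
  cat(sprintf("<anthro_profile> %s, %.2f m, %.1f kg\n", x$sex, x$height,
              x$mass))
  invisible(x)
}

# Axis roles of the intrinsic Z-X-Y joint cardan sequence, by slot.
.axis_slots <- c(flex_ext = 1L, abd_add = 2L, int_ext = 3L)
.slot_axes <- c("flex_ext", "abd_add", "int_ext")

.sides <- c(L = -1, R = 1)

# Segment topology shared by every chain: name, parent, connecting joint.
.topology <- list(
  thorax = list(parent = NA_character_, joint = NA_character_),
  clavicle_L = list(parent = "thorax", joint = "sternoclavicular_L"),
  upper_arm_L = list(parent = "clavicle_L", joint = "shoulder_L"),
  forearm_L = list(parent = "upper_arm_L", joint = "elbow_L"),
  hand_L = list(parent = "forearm_L", joint = "wrist_L"),
  clavicle_R = list(parent = "thorax", joint = "sternoclavicular_R"),
  upper_arm_R = list(parent = "clavicle_R", joint = "shoulder_R"),
  forearm_R = list(parent = "upper_arm_R", joint = "elbow_R"),
  hand_R = list(parent = "forearm_R", joint = "wrist_R")
)

# Free rotation axes per joint type. The sternoclavicular joint keeps
# elevation/depression (abd_add, about the anterior axis) and
# protraction/retraction (int_ext, about the vertical axis): with the
# clavicle's long axis pointing laterally these are the two rotations that
# actually displace the shoulder. Elbow abd_add and wrist int_ext are locked.
.joint_dofs <- list(
  sternoclavicular = c("abd_add", "int_ext"),
  shoulder = c("flex_ext", "abd_add", "int_ext"),
  elbow = c("flex_ext", "int_ext"),
  wrist = c("flex_ext", "abd_add")
)

.read_anthro_table <- function() {
  path <- system.file("extdata", "anthro.csv", package = "boxkin")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Build the full geometry (segment offsets, CoM, markers, joint-center local
# points, landmark pairs) from per-segment lengths. Shared between
# build_chain() and scale_template() so that rescaling regenerates a
# consistent chain. All template segment rotations are the identity: segment
# frames coincide with the global anatomical frame (X anterior, Y up,
# Z right) in the neutral standing posture, so geometry lives entirely in the
# offset vectors.
.build_geometry <- function(profile, lengths, com_frac) {
  H <- profile$height
  Lt <- lengths[["thorax"]]; Lc <- lengths[["clavicle"]]
  Lua <- lengths[["upper_arm"]]; Lfa <- lengths[["forearm"]]
  Lh <- lengths[["hand"]]

  segments <- list(
    thorax = list(offset = c(0, 0, 0), length = Lt,
                  com = c(0, com_frac[["thorax"]] * Lt, 0))
  )
  markers <- list(
    SJN = list(segment = "thorax", local = c(0.034 * H, 0.90 * Lt, 0)),
    SXS = list(segment = "thorax", local = c(0.040 * H, 0.55 * Lt, 0)),
    C7  = list(segment = "thorax", local = c(-0.030 * H, 1.00 * Lt, 0)),
    T8  = list(segment = "thorax", local = c(-0.040 * H, 0.55 * Lt, 0)),
    T10 = list(segment = "thorax", local = c(-0.040 * H, 0.35 * Lt, 0))
  )
  joint_local <- list(
    cervical = list(segment = "thorax", point = c(0, Lt, 0)),
    thoracic = list(segment = "thorax", point = c(0, 0, 0)),
    lumbar = list(segment = "thorax", point = c(0, -0.06 * H, 0))
  )
  landmark_pairs <- list(thorax = c("C7", "T10"))

  for (side in names(.sides)) {
    s <- .sides[[side]]
    seg <- function(base) paste0(base, "_", side)
    mk <- function(base) paste0(side, base)
    segments[[seg("clavicle")]] <- list(
      offset = c(0.012 * H, 0.95 * Lt, s * 0.012 * H), length = Lc,
      com = c(0, 0, s * com_frac[["clavicle"]] * Lc))
    segments[[seg("upper_arm")]] <- list(
      offset = c(0, 0, s * Lc), length = Lua,
      com = c(0, -com_frac[["upper_arm"]] * Lua, 0))
    segments[[seg("forearm")]] <- list(
      offset = c(0, -Lua, 0), length = Lfa,
      com = c(0, -com_frac[["forearm"]] * Lfa, 0))
    segments[[seg("hand")]] <- list(
      offset = c(0, -Lfa, 0), length = Lh,
      com = c(0, -com_frac[["hand"]] * Lh, 0))

    markers[[mk("ACR")]] <- list(segment = seg("clavicle"),
                                 local = c(0, 0.012 * H, s * Lc))
    markers[[mk("UAM")]] <- list(segment = seg("upper_arm"),
                                 local = c(0.005 * H, -0.45 * Lua, s * 0.018 * H))
    markers[[mk("LEP")]] <- list(segment = seg("upper_arm"),
                                 local = c(0, -Lua, s * 0.020 * H))
    markers[[mk("MEP")]] <- list(segment = seg("upper_arm"),
                                 local = c(0, -Lua, -s * 0.020 * H))
    markers[[mk("FAM")]] <- list(segment = seg("forearm"),
                                 local = c(0.005 * H, -0.50 * Lfa, s * 0.015 * H))
    markers[[mk("RSP")]] <- list(segment = seg("forearm"),
                                 local = c(0, -Lfa, s * 0.014 * H))
    markers[[mk("USP")]] <- list(segment = seg("forearm"),
                                 local = c(0, -Lfa, -s * 0.014 * H))
    markers[[mk("HND")]] <- list(segment = seg("hand"),
                                 local = c(0.010 * H, -1.2 * Lh, s * 0.006 * H))

    # Elbow/wrist centers are epicondyle/styloid midpoints by construction;
    # shoulder and spine centers are stored regression-style local points.
    joint_local[[paste0("shoulder_", side)]] <-
      list(segment = seg("clavicle"), point = c(0, 0, s * Lc))
    joint_local[[paste0("elbow_", side)]] <-
      list(segment = seg("upper_arm"), point = c(0, -Lua, 0))
    joint_local[[paste0("wrist_", side)]] <-
      list(segment = seg("forearm"), point = c(0, -Lfa, 0))

    landmark_pairs[[seg("clavicle")]] <- c("SJN", mk("ACR"))
    landmark_pairs[[seg("upper_arm")]] <- c(mk("ACR"), mk("LEP"))
    landmark_pairs[[seg("forearm")]] <- c(mk("LEP"), mk("RSP"))
    landmark_pairs[[seg("hand")]] <- c(mk("RSP"), mk("HND"))
  }
  list(segments = segments, markers = markers, joint_local = joint_local,
       landmark_pairs = landmark_pairs)
}

.joint_list <- function() {
  joints <- list(ground_thorax = list(
    type = "ground", segment = "thorax",
    free_rotations = .slot_axes, free_translations = c("x", "y", "z")))
  for (side in names(.sides)) {
    for (jt in c("sternoclavicular", "shoulder", "elbow", "wrist")) {
      nm <- paste0(jt, "_", side)
      seg <- switch(jt, sternoclavicular = "clavicle", shoulder = "upper_arm",
                    elbow = "forearm", wrist = "hand")
      joints[[nm]] <- list(type = jt, segment = paste0(seg, "_", side),
                           free_rotations = .joint_dofs[[jt]],
                           free_translations = character(0))
    }
  }
  joints
}

.q_names <- function(joints) {
  nm <- c("root.tx", "root.ty", "root.tz", "root.rz", "root.rx", "root.ry")
  for (j in names(joints)) {
    if (j == "ground_thorax") next
    nm <- c(nm, paste0(j, ".", joints[[j]]$free_rotations))
  }
  nm
}

.new_chain <- function(profile, lengths, com_frac, geometry = NULL) {
  if (is.null(geometry))
    geometry <- .build_geometry(profile, lengths, com_frac)
  joints <- .joint_list()
  qn <- .q_names(joints)
  # Per-joint indices into q for the three cardan slots (0 = locked), and a
  # marker-local cache, precomputed for the forward-kinematics hot path.
  joint_qidx <- lapply(names(joints), function(j) {
    idx <- integer(3)
    if (j == "ground_thorax") return(idx)
    for (ax in joints[[j]]$free_rotations)
      idx[.axis_slots[[ax]]] <- match(paste0(j, ".", ax), qn)
    idx
  })
  names(joint_qidx) <- names(joints)
  mlocal <- t(vapply(geometry$markers, function(m) m$local, numeric(3)))
  mseg <- vapply(geometry$markers, function(m) m$segment, character(1))
  # joints on each segment's path to the root (excluding the ground joint),
  # proximal to distal — used by the analytic solver Jacobian
  seg_path <- lapply(names(.topology), function(seg) {
    path <- character(0)
    while (!is.na(.topology[[seg]]$parent)) {
      path <- c(.topology[[seg]]$joint, path)
      seg <- .topology[[seg]]$parent
    }
    path
  })
  names(seg_path) <- names(.topology)
  structure(list(
    profile = profile,
    lengths = lengths,
    com_frac = com_frac,
    segments = geometry$segments,
    topology = .topology,
    joints = joints,
    markers = geometry$markers,
    joint_local = geometry$joint_local,
    landmark_pairs = geometry$landmark_pairs,
    q_names = qn,
    n_q = length(qn),
    joint_qidx = joint_qidx,
    marker_local = mlocal,
    marker_segment = mseg,
    seg_path = seg_path
  ), class = "kinematic_chain")
}

#' Build the upper-extremity kinematic chain
#'
#' Constructs the constrained multibody model used throughout the package:
#' the thorax as six-degree-of-freedom root, and per side a clavicle (2
#' rotational DoF), upper arm (3 DoF ball shoulder), forearm (2 DoF elbow,
#' abduction/adduction locked) and hand (2 DoF wrist, internal/external
#' rotation locked), for 24 generalized coordinates in total. Segment lengths
#' and center-of-mass offsets come from the bundled sex-specific
#' anthropometric table scaled by stature; elbow and wrist joint centers are
#' the epicondyle and styloid midpoints, shoulder and spine centers stored
#' regression-style local points. A documented 21-marker upper-body set is
#' attached to the segments.
#'
#' @param profile an [anthro_profile()].
#' @param overrides optional named list of segment lengths in meters
#'   (names among `thorax`, `clavicle`, `upper_arm`, `forearm`, `hand`)
#'   replacing the table-derived values.
#' @return object of class `kinematic_chain`.
#' @export
#' @examples
#' chain <- build_chain(anthro_profile("male", 1.90, 78))
#' chain$n_q
build_chain <- function(profile, overrides = NULL) {
  if (!inherits(profile, "anthro_profile"))
    profile <- do.call(anthro_profile, as.list(profile))
  tab <- .read_anthro_table()
  tab <- tab[tab$sex == profile$sex, ]
  lengths <- stats::setNames(tab$length_frac_height * profile$height,
                             tab$segment)
  com_frac <- stats::setNames(tab$com_frac_length, tab$segment)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(lengths))
    if (length(bad))
      stop("unknown segment(s) in overrides: ", paste(bad, collapse = ", "),
           call. = FALSE)
    lengths[names(overrides)] <- as.numeric(overrides)
  }
  stopifnot(all(lengths > 0))
  .new_chain(profile, lengths, com_frac)
}

#' @export
print.kinematic_chain <- function(x, ...) {
  cat(sprintf(
    "<kinematic_chain> %d segments, %d joints, n_q = %d, %d markers\n",
    length(x$segments), length(x$joints), x$n_q, length(x$markers)))
  cat(sprintf("  profile: %s, %.2f m, %.1f kg\n", x$profile$sex,
              x$profile$height, x$profile$mass))
  invisible(x)
}

#' Locate generalized coordinates by joint and axis
#'
#' @param chain a [build_chain()] result.
#' @param joint joint name, e.g. `"shoulder_L"`, or `"root"`.
#' @param axis axis name among `flex_ext`, `abd_add`, `int_ext` (or
#'   `tx`/`ty`/`tz`/`rz`/`rx`/`ry` for the root).
#' @return integer index into the q vector.
#' @export
q_index <- function(chain, joint, axis) {
  nm <- paste0(joint, ".", axis)
  i <- match(nm, chain$q_names)
  if (is.na(i))
    stop("no generalized coordinate '", nm, "'", call. = FALSE)
  i
}

#' Zero (template) configuration
#' @param chain a kinematic chain.
#' @return named numeric vector of length `chain$n_q`, all zeros.
#' @export
q_zero <- function(chain) {
  stats::setNames(numeric(chain$n_q), chain$q_names)
}

# Fast forward kinematics: plain list(R, t) per segment, no class validation.
# Used by the solver and everything that iterates over frames.
.fk_fast <- function(chain, q) {
  poses <- vector("list", length(chain$segments))
  names(poses) <- names(chain$segments)
  poses[["thorax"]] <- list(R = cardan_to_matrix(q[4:6], "zxy"), t = q[1:3])
  for (seg in names(chain$topology)) {
    if (seg == "thorax") next
    top <- chain$topology[[seg]]
    idx <- chain$joint_qidx[[top$joint]]
    ang <- c(if (idx[1]) q[idx[1]] else 0,
             if (idx[2]) q[idx[2]] else 0,
             if (idx[3]) q[idx[3]] else 0)
    Rj <- cardan_to_matrix(ang, "zxy")
    par <- poses[[top$parent]]
    poses[[seg]] <- list(
      R = par$R %*% Rj,
      t = as.numeric(par$R %*% chain$segments[[seg]]$offset) + par$t)
  }
  poses
}

# Fast marker projection from .fk_fast output: n_markers x 3 matrix.
.project_fast <- function(chain, poses) {
  labs <- rownames(chain$marker_local)
  out <- matrix(NA_real_, length(labs), 3,
                dimnames = list(labs, c("x", "y", "z")))
  for (i in seq_along(labs)) {
    p <- poses[[chain$marker_segment[[i]]]]
    out[i, ] <- as.numeric(p$R %*% chain$marker_local[i, ]) + p$t
  }
  out
}

#' Forward kinematics
#'
#' Composes per-segment global poses down the tree from a generalized
#' coordinate vector. Locked degrees of freedom contribute zero relative
#' rotation by construction (they are simply absent from q).
#'
#' @param chain a [build_chain()] result.
#' @param q numeric vector of length `chain$n_q` (root translation in m, all
#'   angles in radians).
#' @return named list of [pose()] objects, one per segment.
#' @export
#' @examples
#' chain <- build_chain(anthro_profile("female", 1.63, 59))
#' poses <- forward_kinematics(chain, q_zero(chain))
forward_kinematics <- function(chain, q) {
  q <- as.numeric(q)
  if (length(q) != chain$n_q)
    stop("q has length ", length(q), " but chain expects ", chain$n_q,
         call. = FALSE)
  if (!all(is.finite(q)))
    stop("q contains non-finite values", call. = FALSE)
  lapply(.fk_fast(chain, q), function(p) pose(p$R, p$t))
}

#' Global joint-center positions
#'
#' Maps each joint's stored proximal-frame local point to global coordinates.
#' Elbow and wrist centers are the epicondyle / styloid midpoints; shoulder,
#' cervical, thoracic and lumbar centers the stored regression-derived points.
#'
#' @param poses named list of segment [pose()]s (from [forward_kinematics()]).
#' @param chain the kinematic chain.
#' @param joints optional character vector restricting which joints to return.
#' @return named list of global 3-vectors (meters).
#' @export
joint_centers <- function(poses, chain, joints = NULL) {
  jl <- chain$joint_local
  if (!is.null(joints)) jl <- jl[joints]
  out <- vector("list", length(jl))
  names(out) <- names(jl)
  for (j in names(jl)) {
    seg <- jl[[j]]$segment
    if (is.null(poses[[seg]]))
      stop("missing segment pose '", seg, "' required for joint '", j, "'",
           call. = FALSE)
    out[[j]] <- pose_apply(poses[[seg]], jl[[j]]$point)
  }
  out
}

#' Model-predicted marker positions for one frame
#'
#' Applies each marker's segment pose to its stored local position.
#'
#' @param chain the kinematic chain.
#' @param poses named list of segment poses.
#' @return n_markers x 3 matrix (meters) with marker labels as row names.
#' @export
project_markers <- function(chain, poses) {
  labs <- names(chain$markers)
  out <- matrix(NA_real_, length(labs), 3, dimnames = list(labs, c("x", "y", "z")))
  for (m in labs) {
    seg <- chain$markers[[m]]$segment
    if (is.null(poses[[seg]]))
      stop("missing segment pose '", seg, "' for marker '", m, "'",
           call. = FALSE)
    out[m, ] <- pose_apply(poses[[seg]], chain$markers[[m]]$local)
  }
  out
}

#' Scale the generic template to a subject's static capture
#'
#' Replaces segment lengths by ratio scaling against inter-landmark distances
#' measured in a static frame (each segment has a designated landmark pair,
#' e.g. acromion to lateral epicondyle for the upper arm), then re-derives
#' every marker's segment-local position by a weighted least-squares fit of
#' the scaled chain to the static frame (one multibody kinematic optimization
#' solve). A static frame generated from the chain itself is a fixed point.
#'
#' @param chain the generic [build_chain()] template.
#' @param static_frame a [marker_trajectories()] object; the first frame is
#'   used.
#' @return a new `kinematic_chain` with subject-specific lengths and marker
#'   local positions.
#' @export
scale_template <- function(chain, static_frame) {
  stopifnot(inherits(static_frame, "marker_trajectories"))
  if (n_frames(static_frame) < 1L)
    stop("static frame is empty", call. = FALSE)
  meas <- marker_frame(static_frame, 1L)
  needed <- unique(unlist(chain$landmark_pairs))
  missing <- setdiff(needed, rownames(meas)[stats::complete.cases(meas)])
  if (length(missing))
    stop("static frame lacks landmark marker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  template <- project_markers(chain, forward_kinematics(chain, q_zero(chain)))
  new_lengths <- chain$lengths
  for (seg in names(chain$landmark_pairs)) {
    pair <- chain$landmark_pairs[[seg]]
    d_meas <- sqrt(sum((meas[pair[1], ] - meas[pair[2], ])^2))
    d_temp <- sqrt(sum((template[pair[1], ] - template[pair[2], ])^2))
    base <- sub("_[LR]$", "", seg)
    new_lengths[[base]] <- chain$lengths[[base]] * d_meas / d_temp
  }
  scaled <- .new_chain(chain$profile, new_lengths, chain$com_frac)

  # Re-derive marker local positions from a static MKO fit of the scaled
  # chain to the measured frame.
  fit <- solve_frame(scaled, meas, weights = default_weights(scaled),
                     q_init = static_posture(scaled))
  poses <- forward_kinematics(scaled, fit$q)
  for (m in rownames(meas)) {
    if (is.null(scaled$markers[[m]]) || !all(is.finite(meas[m, ]))) next
    seg <- scaled$markers[[m]]$segment
    scaled$markers[[m]]$local <-
      pose_apply(pose_inverse(poses[[seg]]), meas[m, ])
  }
  scaled
}
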