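# Joint definitions for angle reporting: the shoulder angle is taken between
# thorax and upper arm (the clavicle's small rotations fold into it, as in
# segment-based reporting), elbow between upper arm and forearm, wrist between
# forearm and hand. Elbow abd_add and wrist int_ext are locked in the model
# and therefore never reported.
.angle_joints <- list(
  shoulder = list(parent = "thorax", child = "upper_arm",
                  locked = character(0)),
  elbow = list(parent = "upper_arm", child = "forearm", locked = "abd_add"),
  wrist = list(parent = "forearm", child = "hand", locked = "int_ext")
)

# Sign convention: flexion, abduction and internal rotation positive on both
# sides. With right-handed segment axes shared across sides, the
# abduction/adduction and internal/external raw angles mirror between left
# and right.
.axis_sign <- function(axis, side) {
  switch(axis,
         flex_ext = 1,
         abd_add = if (side == "L") 1 else -1,
         int_ext = if (side == "L") -1 else 1)
}

.side_label <- function(side, front_side) {
  ifelse(side == front_side, "front", "rear")
}

#' Joint angle series from a pose stream
#'
#' Decomposes the relative parent-to-child segment rotations of a
#' [pose_stream()] into intrinsic cardan angles (default Z-X-Y:
#' flexion/extension, abduction/adduction, internal/external rotation) for
#' the shoulder, elbow and wrist of both sides. Locked model axes (elbow
#' abduction/adduction, wrist internal/external rotation) are reported as
#' `NA`. Angles follow the convention flexion/abduction/internal positive on
#' both sides, in degrees.
#'
#' @param stream a [pose_stream()].
#' @param sequence cardan sequence, default `"zxy"`; configurable per the
#'   frame conventions of other systems.
#' @param front_side which anatomical side is the lead (front) arm, `"L"`
#'   (orthodox stance, default) or `"R"`.
#' @return tibble with columns `joint`, `side` (`front`/`rear`), `axis`,
#'   `frame`, `time_s`, `value_deg`, `valid` (false at invalid stream frames
#'   or within 1 degree of gimbal lock).
#' @export
joint_angles <- function(stream, sequence = "zxy", front_side = "L") {
  stopifnot(inherits(stream, "pose_stream"), front_side %in% c("L", "R"))
  nf <- n_frames(stream)
  tt <- time_axis(stream)
  out <- vector("list", 0)
  for (jt in names(.angle_joints)) {
    def <- .angle_joints[[jt]]
    for (side in c("L", "R")) {
      pseg <- if (def$parent == "thorax") "thorax" else paste0(def$parent, "_", side)
      cseg <- paste0(def$child, "_", side)
      vals <- matrix(NA_real_, nf, 3)
      gimbal <- rep(FALSE, nf)
      for (f in seq_len(nf)) {
        if (!stream$valid[f]) next
        Rp <- stream$T[1:3, 1:3, pseg, f]
        Rc <- stream$T[1:3, 1:3, cseg, f]
        a <- cardan_angles(Rp, Rc, sequence = sequence)
        vals[f, ] <- a
        gimbal[f] <- attr(a, "gimbal")
      }
      for (slot in 1:3) {
        axis <- .slot_axes[slot]
        deg <- if (axis %in% def$locked) rep(NA_real_, nf) else
          vals[, slot] * .axis_sign(axis, side) * 180 / pi
        out[[length(out) + 1L]] <- tibble::tibble(
          joint = jt, side = .side_label(side, front_side), axis = axis,
          frame = seq_len(nf), time_s = tt, value_deg = deg,
          valid = stream$valid & !gimbal & !(axis %in% def$locked))
      }
    }
  }
  do.call(rbind, out)
}

#' 3D distances between corresponding joint centers of two pose streams
#'
#' Per frame Euclidean distance between the joint centers (shoulder, elbow,
#' wrist, both sides) computed from two time-aligned pose streams of equal
#' length, e.g. a marker-based and a markerless stream. Joint centers are
#' retrieved from the pose matrices as the origin of the joint's distal
#' segment frame, which for chain-consistent streams coincides with the
#' anatomical (proximal-frame) definition of [joint_centers()].
#'
#' @param stream_a,stream_b [pose_stream()]s, time-aligned and equal length
#'   (see [resample_align()]).
#' @param chain the shared kinematic chain defining joint-center local
#'   points.
#' @param front_side lead arm, `"L"` or `"R"`.
#' @return tibble with columns `joint`, `side`, `frame`, `time_s`,
#'   `distance_m`.
#' @export
joint_center_distance <- function(stream_a, stream_b, chain,
                                  front_side = "L") {
  if (n_frames(stream_a) != n_frames(stream_b))
    stop("streams differ in length (", n_frames(stream_a), " vs ",
         n_frames(stream_b), "); align them with resample_align() first",
         call. = FALSE)
  nf <- n_frames(stream_a)
  tt <- time_axis(stream_a)
  joints <- c("shoulder", "elbow", "wrist")
  out <- vector("list", 0)
  for (jt in joints) {
    for (side in c("L", "R")) {
      jname <- paste0(jt, "_", side)
      seg <- chain$joints[[jname]]$segment  # distal segment; its origin is
                                            # the joint center
      d <- rep(NA_real_, nf)
      ok <- stream_a$valid & stream_b$valid
      for (f in which(ok)) {
        ca <- stream_a$T[1:3, 4, seg, f]
        cb <- stream_b$T[1:3, 4, seg, f]
        d[f] <- sqrt(sum((ca - cb)^2))
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        joint = jt, side = .side_label(side, front_side),
        frame = seq_len(nf), time_s = tt, distance_m = d)
    }
  }
  do.call(rbind, out)
}

#' Segment center-of-mass speeds
#'
#' Maps each segment's center-of-mass offset through its pose to global
#' coordinates and differentiates by central finite differences (one-sided at
#' the ends), returning speed magnitudes.
#'
#' @param stream a [pose_stream()] (needs at least 3 frames).
#' @param chain the kinematic chain (provides CoM offsets).
#' @param segments optional subset of segment names.
#' @param front_side lead arm, `"L"` or `"R"`.
#' @return tibble with columns `segment` (class name), `side` (`front`,
#'   `rear`, or `""` for the thorax), `frame`, `time_s`, `speed_mps`.
#' @export
com_speed <- function(stream, chain, segments = NULL, front_side = "L") {
  stopifnot(inherits(stream, "pose_stream"))
  if (is.null(stream$rate) || !is.finite(stream$rate))
    stop("pose stream carries no sampling rate", call. = FALSE)
  nf <- n_frames(stream)
  if (nf < 3L) stop("need at least 3 frames to differentiate", call. = FALSE)
  if (is.null(segments)) segments <- stream$segments
  tt <- time_axis(stream)
  out <- vector("list", 0)
  for (seg in segments) {
    com <- c(chain$segments[[seg]]$com, 1)
    p <- t(vapply(seq_len(nf),
                  function(f) as.numeric(stream$T[1:3, , seg, f] %*% com),
                  numeric(3)))
    v <- matrix(NA_real_, nf, 3)
    v[1, ] <- (p[2, ] - p[1, ]) * stream$rate
    v[nf, ] <- (p[nf, ] - p[nf - 1, ]) * stream$rate
    if (nf > 2L)
      v[2:(nf - 1), ] <- (p[3:nf, , drop = FALSE] -
                            p[1:(nf - 2), , drop = FALSE]) * stream$rate / 2
    speed <- sqrt(rowSums(v^2))
    speed[!stream$valid] <- NA_real_
    base <- sub("_[LR]$", "", seg)
    side <- if (grepl("_[LR]$", seg))
      .side_label(sub("^.*_", "", seg), front_side) else ""
    out[[length(out) + 1L]] <- tibble::tibble(
      segment = base, side = side, frame = seq_len(nf), time_s = tt,
      speed_mps = speed)
  }
  do.call(rbind, out)
}

#' Low-pass Butterworth filter specification
#'
#' @param order filter order per pass (default 4).
#' @param cutoff cutoff frequency in Hz (default 8).
#' @param zero_phase apply forward-backward for zero phase lag (default
#'   `TRUE`). No cutoff correction is applied for the dual pass: the
#'   documented contract is -6 dB at the cutoff.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff = 8, zero_phase = TRUE) {
  stopifnot(order >= 1, cutoff > 0)
  structure(list(order = order, cutoff = cutoff, zero_phase = zero_phase),
            class = "filter_spec")
}

# Odd (endpoint-anchored) reflective padding, as used before zero-phase
# filtering to suppress edge transients.
.reflect_pad <- function(x, np) {
  n <- length(x)
  np <- min(np, n - 1L)
  c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
}

# One IIR pass started in steady state for the signal's first value, so a
# constant input passes through exactly (unit DC gain to round-off).
.iir_pass <- function(x, ba) {
  as.numeric(signal::filter(ba$b, ba$a, x,
                            init.x = rep(x[1], length(ba$b) - 1L),
                            init.y = rep(x[1], length(ba$a) - 1L)))
}

.filter_run <- function(x, ba, np, zero_phase) {
  xp <- .reflect_pad(x, np)
  y <- .iir_pass(xp, ba)
  if (zero_phase)
    y <- rev(.iir_pass(rev(y), ba))
  np <- min(np, length(x) - 1L)
  y[(np + 1):(np + length(x))]
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies the configured low-pass Butterworth filter forward-backward (zero
#' phase) with odd reflective padding of at least three filter time
#' constants. `NA` gaps are preserved and the finite runs filtered piecewise;
#' runs shorter than the padding are left unfiltered with a warning.
#'
#' @param x numeric vector (a sampled signal), possibly with `NA` gaps.
#' @param rate sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return filtered numeric vector, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 300)
#' x <- sin(2 * pi * 2 * t) + sin(2 * pi * 40 * t)
#' y <- butterworth(x, 300, filter_spec(cutoff = 8))
butterworth <- function(x, rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), rate > 0)
  if (spec$cutoff >= rate / 2)
    stop("cutoff (", spec$cutoff, " Hz) must be below the Nyquist frequency (",
         rate / 2, " Hz)", call. = FALSE)
  fin <- is.finite(x)
  if (!any(fin)) return(x)
  ba <- signal::butter(spec$order, spec$cutoff / (rate / 2), type = "low")
  np <- ceiling(3 * rate / spec$cutoff)
  if (all(fin) && length(x) <= np)
    stop("signal (", length(x), " samples) is shorter than the required ",
         "padding (", np, " samples)", call. = FALSE)
  runs <- rle(fin)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  y <- x
  short_runs <- 0L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    idx <- starts[k]:ends[k]
    if (length(idx) <= max(12L, 3L * spec$order)) {
      short_runs <- short_runs + 1L
      next
    }
    y[idx] <- .filter_run(x[idx], ba, np, spec$zero_phase)
  }
  if (short_runs > 0L)
    warning(short_runs, " gap-bounded run(s) too short to filter; ",
            "left unfiltered", call. = FALSE)
  y
}

#' Resample a series onto a lower-rate time grid
#'
#' Anti-alias low-pass filters (zero-phase Butterworth at 45% of the target
#' rate) and then interpolates the series onto the target timestamps,
#' aligning e.g. a 300 Hz marker-derived series with a 60 Hz markerless
#' stream. Identical rates return the input unchanged.
#'
#' @param x numeric vector sampled at `rate`.
#' @param rate source sampling rate, Hz.
#' @param target_rate target sampling rate, Hz (must not exceed `rate`).
#' @param start_time time of the first sample, s.
#' @param target_time optional explicit target timestamps (must lie within
#'   the source time range).
#' @return list with `x` (resampled values) and `time` (target timestamps).
#' @export
resample_align <- function(x, rate, target_rate, start_time = 0,
                           target_time = NULL) {
  stopifnot(rate > 0, target_rate > 0)
  if (target_rate > rate)
    stop("cannot upsample: target rate exceeds source rate", call. = FALSE)
  t_src <- start_time + (seq_along(x) - 1L) / rate
  if (is.null(target_time)) {
    target_time <- seq(start_time, t_src[length(t_src)], by = 1 / target_rate)
  }
  if (min(target_time) < min(t_src) - 1e-9 ||
      max(target_time) > max(t_src) + 1e-9)
    stop("target timestamps fall outside the source time range",
         call. = FALSE)
  if (abs(rate - target_rate) < 1e-9 &&
      length(target_time) == length(x) &&
      max(abs(target_time - t_src)) < 1e-9)
    return(list(x = x, time = t_src))
  if (!any(is.finite(x)))  # fully masked series (e.g. locked axes)
    return(list(x = rep(NA_real_, length(target_time)), time = target_time))
  xf <- butterworth(x, rate, filter_spec(order = 4,
                                         cutoff = 0.45 * target_rate,
                                         zero_phase = TRUE))
  list(x = stats::approx(t_src, xf, xout = target_time, rule = 1)$y,
       time = target_time)
}
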