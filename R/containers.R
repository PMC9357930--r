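#' Labeled 3D marker trajectories
#'
#' Time series of labeled 3D points with a sampling rate and optional
#' per-marker weights. Positions are stored as an `n_frames x n_markers x 3`
#' array in meters; gaps are `NA`.
#'
#' @param pos numeric array `n_frames x n_markers x 3` (meters) with marker
#'   labels as the second dimnames, or an `n_markers x 3` matrix for a single
#'   frame.
#' @param rate sampling rate in Hz.
#' @param start_time time of the first frame in seconds (default 0).
#' @return object of class `marker_trajectories`.
#' @export
marker_trajectories <- function(pos, rate, start_time = 0) {
  if (is.matrix(pos)) {
    labs <- rownames(pos)
    pos <- array(pos, dim = c(1L, nrow(pos), 3L),
                 dimnames = list(NULL, labs, c("x", "y", "z")))
  }
  stopifnot(is.array(pos), length(dim(pos)) == 3L, dim(pos)[3] == 3L,
            is.numeric(rate), length(rate) == 1L, rate > 0)
  if (is.null(dimnames(pos)[[2]]))
    stop("marker labels are required (dimnames on the second dimension)",
         call. = FALSE)
  dimnames(pos)[[3]] <- c("x", "y", "z")
  structure(list(pos = pos, rate = as.numeric(rate),
                 start_time = as.numeric(start_time)),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("<marker_trajectories> %d frames x %d markers @ %g Hz\n",
              dim(x$pos)[1], dim(x$pos)[2], x$rate))
  cat("  markers:", paste(utils::head(marker_labels(x), 8), collapse = ", "),
      if (dim(x$pos)[2] > 8) "..." else "", "\n")
  invisible(x)
}

#' Accessors for trajectory containers
#'
#' `n_frames()` returns the frame count, `marker_labels()` the marker names,
#' `time_axis()` the frame timestamps in seconds, `marker_frame()` one frame
#' as an `n_markers x 3` matrix.
#'
#' @param x a `marker_trajectories`, `pose_stream` or `q_trajectory`.
#' @param i frame index.
#' @return see each function's description.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.marker_trajectories <- function(x) dim(x$pos)[1]

#' @export
n_frames.pose_stream <- function(x) dim(x$T)[4]

#' @export
n_frames.q_trajectory <- function(x) nrow(x$q)

#' @rdname n_frames
#' @export
marker_labels <- function(x) dimnames(x$pos)[[2]]

#' @rdname n_frames
#' @export
time_axis <- function(x) {
  n <- n_frames(x)
  (x$start_time %||% 0) + (seq_len(n) - 1L) / x$rate
}

#' @rdname n_frames
#' @export
marker_frame <- function(x, i) {
  stopifnot(inherits(x, "marker_trajectories"), i >= 1, i <= n_frames(x))
  m <- x$pos[i, , , drop = FALSE]
  matrix(m, dim(x$pos)[2], 3,
         dimnames = list(dimnames(x$pos)[[2]], c("x", "y", "z")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-segment pose time series
#'
#' Stores per-frame 4x4 homogeneous transforms of each body segment in the
#' global frame, as exported by markerless systems and by
#' [export_poses()]. Internally a `4 x 4 x n_segments x n_frames` array.
#'
#' @param T array `4 x 4 x n_segments x n_frames` with segment names as the
#'   third dimnames.
#' @param rate sampling rate in Hz.
#' @param start_time time of the first frame in seconds.
#' @param valid optional logical vector flagging frames with a trusted pose
#'   estimate (default all `TRUE`).
#' @return object of class `pose_stream`.
#' @export
pose_stream <- function(T, rate, start_time = 0, valid = NULL) {
  stopifnot(is.array(T), length(dim(T)) == 4L, all(dim(T)[1:2] == 4L),
            rate > 0)
  if (dim(T)[3] > 0L && is.null(dimnames(T)[[3]]))
    stop("segment names are required (dimnames on the third dimension)",
         call. = FALSE)
  nf <- dim(T)[4]
  if (is.null(valid)) valid <- rep(TRUE, nf)
  stopifnot(length(valid) == nf)
  structure(list(T = T, rate = as.numeric(rate),
                 start_time = as.numeric(start_time),
                 segments = dimnames(T)[[3]], valid = valid),
            class = "pose_stream")
}

#' @export
print.pose_stream <- function(x, ...) {
  cat(sprintf("<pose_stream> %d frames x %d segments @ %g Hz\n",
              n_frames(x), length(x$segments), x$rate))
  cat("  segments:", paste(x$segments, collapse = ", "), "\n")
  if (!all(x$valid))
    cat(sprintf("  %d invalid frame(s)\n", sum(!x$valid)))
  invisible(x)
}

#' Extract one segment pose from a stream
#' @param stream a [pose_stream()].
#' @param segment segment name.
#' @param i frame index.
#' @return a [pose()].
#' @export
stream_pose <- function(stream, segment, i) {
  pose(stream$T[, , segment, i])
}

# Assemble a pose_stream from a list (frames) of .fk_fast-style pose lists.
.poses_to_stream <- function(pose_frames, segments, rate, start_time = 0,
                             valid = NULL) {
  nf <- length(pose_frames)
  T <- array(NA_real_, c(4, 4, length(segments), nf),
             dimnames = list(NULL, NULL, segments, NULL))
  for (f in seq_len(nf)) {
    pf <- pose_frames[[f]]
    if (is.null(pf)) next
    for (s in seq_along(segments)) {
      p <- pf[[segments[s]]]
      T[, , s, f] <- rbind(cbind(p$R, p$t), c(0, 0, 0, 1))
    }
  }
  pose_stream(T, rate, start_time, valid)
}

#' Generalized-coordinate trajectory
#'
#' Time series of the chain's generalized coordinates (root pose plus free
#' joint angles), the solution space of multibody kinematic optimization and
#' the ground truth of the synthetic generator.
#'
#' @param q numeric matrix `n_frames x n_q` with coordinate names as column
#'   names.
#' @param rate sampling rate in Hz.
#' @param start_time time of the first frame in seconds.
#' @param valid optional per-frame logical flag (frames that could not be
#'   solved are `FALSE`, never interpolated).
#' @return object of class `q_trajectory`.
#' @export
q_trajectory <- function(q, rate, start_time = 0, valid = NULL) {
  stopifnot(is.matrix(q), rate > 0)
  if (is.null(valid)) valid <- rep(TRUE, nrow(q))
  stopifnot(length(valid) == nrow(q))
  structure(list(q = q, rate = as.numeric(rate),
                 start_time = as.numeric(start_time), valid = valid),
            class = "q_trajectory")
}

#' @export
print.q_trajectory <- function(x, ...) {
  cat(sprintf("<q_trajectory> %d frames x %d coordinates @ %g Hz\n",
              nrow(x$q), ncol(x$q), x$rate))
  invisible(x)
}
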