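#' Elementary rotation matrices
#'
#' Right-handed rotations about the segment-frame axes. Axis roles follow the
#' joint coordinate convention used throughout the package: Z is the
#' mediolateral axis (flexion/extension), X the anterior axis
#' (abduction/adduction) and Y the longitudinal axis (internal/external
#' rotation).
#'
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0,
           0, c_, s_,
           0, -s_, c_), 3, 3)
}

#' @rdname elementary-rotations
rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_,
           0, 1, 0,
           s_, 0, c_), 3, 3)
}

#' @rdname elementary-rotations
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0,
           -s_, c_, 0,
           0, 0, 1), 3, 3)
}

#' Compose a rotation matrix from cardan angles
#'
#' Builds the rotation `Rz(a1) %*% Rx(a2) %*% Ry(a3)` for the intrinsic Z-X-Y
#' cardan sequence (flexion/extension, abduction/adduction, internal/external
#' rotation), the package default for every joint and the root orientation.
#' Alternative orders are accepted as a three-character string such as
#' `"xyz"`.
#'
#' @param angles numeric length-3 vector of angles in radians, in sequence
#'   order.
#' @param sequence three-character axis string, default `"zxy"`.
#' @return 3x3 rotation matrix.
#' @export
#' @examples
#' cardan_to_matrix(c(pi / 4, 0, 0))
cardan_to_matrix <- function(angles, sequence = "zxy") {
  stopifnot(length(angles) == 3L, is.finite(angles))
  ax <- strsplit(tolower(sequence), "")[[1]]
  if (length(ax) != 3L || anyDuplicated(ax) || !all(ax %in% c("x", "y", "z")))
    stop("`sequence` must be a permutation of 'x', 'y', 'z'", call. = FALSE)
  rots <- list(x = rot_x, y = rot_y, z = rot_z)
  rots[[ax[1]]](angles[1]) %*% rots[[ax[2]]](angles[2]) %*% rots[[ax[3]]](angles[3])
}

#' Decompose a relative rotation into cardan angles
#'
#' Inverse of [cardan_to_matrix()]: extracts the ordered intrinsic cardan
#' angles of the rotation carrying a parent frame onto a child frame. When two
#' poses are supplied the relative rotation `t(R_parent) %*% R_child` is
#' decomposed. Frames whose middle angle is within `lock_tol` of +/- 90
#' degrees sit near gimbal lock where the first and third angles are poorly
#' conditioned; these are reported through the `gimbal` attribute.
#'
#' @param parent 3x3 rotation (or a `pose`, see [pose()]) of the parent
#'   segment; if `child` is `NULL`, `parent` is taken to be the relative
#'   rotation itself.
#' @param child optional 3x3 rotation or `pose` of the child segment.
#' @param sequence cardan sequence string, default `"zxy"`.
#' @param lock_tol gimbal-lock flag tolerance in radians (default 1 degree).
#' @return numeric length-3 vector of angles (radians) in sequence order, with
#'   a logical attribute `"gimbal"`.
#' @export
#' @examples
#' a <- c(0.3, -0.2, 0.7)
#' all.equal(as.numeric(cardan_angles(cardan_to_matrix(a))), a)
cardan_angles <- function(parent, child = NULL, sequence = "zxy",
                          lock_tol = pi / 180) {
  R1 <- if (inherits(parent, "pose")) parent$R else parent
  if (!is_rotation(R1))
    stop("`parent` is not a valid rotation matrix", call. = FALSE)
  if (is.null(child)) {
    R <- R1
  } else {
    R2 <- if (inherits(child, "pose")) child$R else child
    if (!is_rotation(R2))
      stop("`child` is not a valid rotation matrix", call. = FALSE)
    R <- t(R1) %*% R2
  }
  ax <- strsplit(tolower(sequence), "")[[1]]
  idx <- match(ax, c("x", "y", "z"))
  # Generic intrinsic i-j-k (i, j, k distinct). Sign of the middle-angle term
  # depends on the cyclic parity of the sequence.
  i <- idx[1]; j <- idx[2]; k <- idx[3]
  cyclic <- (j - i) %% 3 == 1   # e.g. x-y-z, y-z-x, z-x-y
  sgn <- if (cyclic) 1 else -1
  s2 <- sgn * R[i, k]
  s2 <- max(-1, min(1, s2))
  a2 <- asin(s2)
  if (abs(abs(a2) - pi / 2) < lock_tol) {
    gimbal <- TRUE
    # a1 and a3 are degenerate (only their sum/difference is defined);
    # conventionally put it all in a1.
    a1 <- atan2(sgn * R[j, i], R[j, j])
    a3 <- 0
  } else {
    gimbal <- FALSE
    a1 <- atan2(-sgn * R[j, k], R[k, k])
    a3 <- atan2(-sgn * R[i, j], R[i, i])
  }
  out <- c(a1, a2, a3)
  attr(out, "gimbal") <- gimbal
  out
}

#' Test for a proper rotation matrix
#'
#' @param R matrix to test.
#' @param tol orthonormality and determinant tolerance.
#' @return `TRUE` if `R` is 3x3, orthonormal and with determinant +1 within
#'   `tol`.
#' @export
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

#' Homogeneous rigid-body pose
#'
#' A pose couples a rotation `R` and a translation `t` (meters), equivalently
#' a 4x4 homogeneous matrix with last row (0, 0, 0, 1). Construction validates
#' the rotation invariants.
#'
#' @param R 3x3 rotation matrix, or a 4x4 homogeneous matrix (then `t` must be
#'   missing).
#' @param t translation 3-vector in meters.
#' @return object of class `pose` with elements `R` and `t`.
#' @export
#' @examples
#' p <- pose(diag(3), c(0, 1, 0))
#' as.matrix(p)
pose <- function(R = diag(3), t = c(0, 0, 0)) {
  if (is.matrix(R) && all(dim(R) == c(4L, 4L))) {
    if (max(abs(R[4, ] - c(0, 0, 0, 1))) > 1e-9)
      stop("last row of a homogeneous matrix must be (0,0,0,1)", call. = FALSE)
    t <- R[1:3, 4]
    R <- R[1:3, 1:3]
  }
  if (!is_rotation(R))
    stop("R is not a proper rotation (orthonormal, det +1, within 1e-9)",
         call. = FALSE)
  stopifnot(length(t) == 3L, all(is.finite(t)))
  structure(list(R = R, t = as.numeric(t)), class = "pose")
}

#' @export
as.matrix.pose <- function(x, ...) {
  m <- diag(4)
  m[1:3, 1:3] <- x$R
  m[1:3, 4] <- x$t
  m
}

#' @export
print.pose <- function(x, ...) {
  cat("<pose>\n")
  print(round(as.matrix(x), 6))
  invisible(x)
}

#' Compose two poses (parent then child-relative)
#' @param a,b poses; the result maps child-local coordinates through `b` then
#'   `a`.
#' @return a `pose`.
#' @export
pose_compose <- function(a, b) {
  pose(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Apply a pose to points
#' @param p a `pose`.
#' @param x 3-vector or an n x 3 matrix of points (meters).
#' @return transformed points, same shape as `x`.
#' @export
pose_apply <- function(p, x) {
  if (is.matrix(x)) {
    sweep(x %*% t(p$R), 2, -p$t)
  } else {
    as.numeric(p$R %*% x) + p$t
  }
}

#' Invert a pose
#' @param p a `pose`.
#' @return the inverse `pose`.
#' @export
pose_inverse <- function(p) {
  pose(t(p$R), as.numeric(-t(p$R) %*% p$t))
}
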