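#' Segment-grouped marker weighting scheme
#'
#' Builds per-marker weights from per-segment-class weights. The default
#' ordering puts the highest weight at the thorax, followed by the upper arm,
#' forearm, and hand, reflecting decreasing confidence in skin markers toward
#' the distal end of the chain; the clavicle (acromion marker) shares the
#' upper-arm weight.
#'
#' @param chain a [build_chain()] result.
#' @param thorax,clavicle,upper_arm,forearm,hand non-negative weights per
#'   segment class.
#' @return named numeric vector of per-marker weights.
#' @export
#' @examples
#' chain <- build_chain(anthro_profile("male", 1.72, 54))
#' default_weights(chain)
weight_scheme <- function(chain, thorax = 10, clavicle = 5, upper_arm = 5,
                          forearm = 2, hand = 1) {
  w <- c(thorax = thorax, clavicle = clavicle, upper_arm = upper_arm,
         forearm = forearm, hand = hand)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  base <- sub("_[LR]$", "", chain$marker_segment)
  stats::setNames(as.numeric(w[base]), names(chain$marker_segment))
}

#' @rdname weight_scheme
#' @export
default_weights <- function(chain) weight_scheme(chain)

#' Static initializing posture
#'
#' Anatomical standing posture with the elbows flexed to 90 degrees, the
#' classical guard-like initialization for the first frame of a trial.
#'
#' @param chain a kinematic chain.
#' @return named q vector.
#' @export
static_posture <- function(chain) {
  q <- q_zero(chain)
  q[q_index(chain, "elbow_L", "flex_ext")] <- pi / 2
  q[q_index(chain, "elbow_R", "flex_ext")] <- pi / 2
  q
}

# Box bounds on the generalized coordinates: +/- 10 m on root translation,
# +/- pi on all free angles except elbow flexion, restricted to [0, 160 deg]
# for anatomical plausibility (prevents mirror solutions).
.q_bounds <- function(chain) {
  n <- chain$n_q
  lower <- rep(-pi, n); upper <- rep(pi, n)
  lower[1:3] <- -10; upper[1:3] <- 10
  for (side in c("L", "R")) {
    i <- q_index(chain, paste0("elbow_", side), "flex_ext")
    lower[i] <- 0
    upper[i] <- 160 * pi / 180
  }
  names(lower) <- names(upper) <- chain$q_names
  list(lower = lower, upper = upper)
}

# Validate and subset one frame of measured markers against the chain.
# Returns labels actually usable (known, finite, positive weight).
.usable_markers <- function(chain, meas, weights, warn = TRUE) {
  labs <- rownames(meas)
  unknown <- setdiff(labs, names(chain$markers))
  if (length(unknown) && warn)
    warning("ignoring unlabeled marker(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  labs <- intersect(labs, names(chain$markers))
  finite <- labs[apply(meas[labs, , drop = FALSE], 1, function(r) all(is.finite(r)))]
  if (length(finite) < length(labs) && warn)
    warning("excluding ", length(labs) - length(finite),
            " marker(s) with missing coordinates", call. = FALSE)
  w <- weights[finite]
  finite[!is.na(w) & w > 0]
}

.collinear <- function(pts) {
  if (nrow(pts) < 3L) return(TRUE)
  c0 <- colMeans(pts)
  sv <- svd(sweep(pts, 2, c0))$d
  sv[2] < 1e-10 * max(sv[1], 1e-12)
}

#' Fit the chain to one frame of markers (multibody kinematic optimization)
#'
#' Minimizes the weighted sum of squared distances between measured markers
#' and their model-predicted positions over the chain's free generalized
#' coordinates, using bounded Levenberg-Marquardt trust-region nonlinear
#' least squares. Locked degrees of freedom never enter the parameter vector,
#' so joint constraints are satisfied exactly by construction.
#'
#' @param chain a [build_chain()] result.
#' @param meas one frame of measured markers: `n x 3` matrix with labels as
#'   row names (meters), or a one-frame [marker_trajectories()].
#' @param weights named per-marker weights (see [weight_scheme()]).
#' @param q_init starting coordinate vector.
#' @param free optional logical mask of length `chain$n_q`; coordinates with
#'   `FALSE` are frozen at their `q_init` value (used e.g. for planar
#'   reductions).
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return list with elements `q` (named solution vector), and `report`
#'   (objective value, per-marker residual norms in meters, iteration count,
#'   convergence flag).
#' @export
solve_frame <- function(chain, meas, weights = default_weights(chain),
                        q_init = static_posture(chain), free = NULL,
                        control = NULL) {
  if (inherits(meas, "marker_trajectories")) meas <- marker_frame(meas, 1L)
  stopifnot(is.matrix(meas), ncol(meas) == 3L, !is.null(rownames(meas)))
  if (length(q_init) != chain$n_q)
    stop("q_init has wrong length", call. = FALSE)
  use <- .usable_markers(chain, meas, weights)
  if (length(use) < 3L || .collinear(meas[use, , drop = FALSE]))
    stop("need at least 3 non-collinear weighted markers; got ",
         length(use), call. = FALSE)
  fit <- .lm_fit(chain, meas[use, , drop = FALSE], weights[use],
                 as.numeric(q_init), free, control)
  list(q = stats::setNames(fit$q, chain$q_names), report = fit$report)
}

# Core LM fit shared by solve_frame and solve_trajectory.
#
# A near-straight arm makes the shoulder and elbow internal-rotation axes
# almost parallel, so the marker objective develops nearly flat valleys and a
# pure least-squares minimizer can slide along them from frame to frame. A
# tiny ridge toward the warm start (lambda, in weighted-residual units)
# selects the continuity-preserving solution on those valleys; a final
# unregularized polish pass removes the (already negligible) ridge bias, so
# clean data are still recovered exactly. Reported objectives contain the
# marker term only.
.lm_fit <- function(chain, meas, w, q_init, free, control, lambda = 1e-9) {
  if (is.null(free)) free <- rep(TRUE, chain$n_q)
  stopifnot(length(free) == chain$n_q)
  bounds <- .q_bounds(chain)
  q_full <- pmin(pmax(q_init, bounds$lower), bounds$upper)
  sw <- sqrt(w)
  labs <- match(rownames(meas), rownames(chain$marker_local))
  segs <- chain$marker_segment[labs]
  locals <- chain$marker_local[labs, , drop = FALSE]
  q_ref <- q_full[free]
  nm <- nrow(meas)

  make_resid <- function(lam) {
    sl <- sqrt(lam)
    function(par) {
      q_full[free] <- par
      poses <- .fk_fast(chain, q_full)
      r <- numeric(3L * nm)
      for (i in seq_len(nm)) {
        p <- poses[[segs[i]]]
        pred <- p$R %*% locals[i, ] + p$t
        r[(3 * i - 2):(3 * i)] <- sw[i] * (pred - meas[i, ])
      }
      if (lam > 0) c(r, sl * (par - q_ref)) else r
    }
  }

  # Analytic geometric Jacobian: the derivative of a marker position with
  # respect to a rotational coordinate is axis x (p - center), with the axis
  # directions of the intrinsic Z-X-Y sequence evaluated at the current
  # configuration. Exact gradients keep the solver honest near zero residual,
  # where forward differences drown in round-off.
  make_jac <- function(lam) {
    sl <- sqrt(lam)
    free_idx <- which(free)
    col_of <- match(seq_len(chain$n_q), free_idx)  # q index -> jac column
    function(par) {
      q_full[free] <- par
      poses <- .fk_fast(chain, q_full)
      # per-joint rotation axes (global) and centers
      ax_list <- vector("list", length(chain$joints))
      names(ax_list) <- names(chain$joints)
      c1 <- cos(q_full[4]); s1 <- sin(q_full[4])
      c2 <- cos(q_full[5]); s2 <- sin(q_full[5])
      ax_list[["ground_thorax"]] <- list(
        axes = cbind(c(0, 0, 1),
                     c(c1, s1, 0),
                     c(-s1 * c2, c1 * c2, s2)),
        center = q_full[1:3])
      for (seg in names(chain$topology)) {
        if (seg == "thorax") next
        jn <- chain$topology[[seg]]$joint
        Rp <- poses[[chain$topology[[seg]]$parent]]$R
        idx <- chain$joint_qidx[[jn]]
        b1 <- if (idx[1]) q_full[idx[1]] else 0
        b2 <- if (idx[2]) q_full[idx[2]] else 0
        ax_list[[jn]] <- list(
          axes = cbind(Rp[, 3],
                       Rp %*% c(cos(b1), sin(b1), 0),
                       Rp %*% c(-sin(b1) * cos(b2), cos(b1) * cos(b2),
                                sin(b2))),
          center = poses[[seg]]$t)
      }
      nr <- 3L * nm + if (lam > 0) length(par) else 0L
      J <- matrix(0, nr, length(par))
      for (i in seq_len(nm)) {
        p <- poses[[segs[i]]]
        pm <- as.numeric(p$R %*% locals[i, ]) + p$t
        rows <- (3 * i - 2):(3 * i)
        # root translation
        for (k in 1:3) if (free[k]) J[rows[k], col_of[k]] <- sw[i]
        # root rotation
        g <- ax_list[["ground_thorax"]]
        for (s_ in 1:3) {
          qi <- 3L + s_
          if (!free[qi]) next
          a <- g$axes[, s_]
          lever <- pm - g$center
          J[rows, col_of[qi]] <- sw[i] * c(
            a[2] * lever[3] - a[3] * lever[2],
            a[3] * lever[1] - a[1] * lever[3],
            a[1] * lever[2] - a[2] * lever[1])
        }
        # joints on the path to this marker's segment
        for (jn in chain$seg_path[[segs[i]]]) {
          idx <- chain$joint_qidx[[jn]]
          aj <- ax_list[[jn]]
          lever <- pm - aj$center
          for (s_ in 1:3) {
            qi <- idx[s_]
            if (!qi || !free[qi]) next
            a <- aj$axes[, s_]
            J[rows, col_of[qi]] <- sw[i] * c(
              a[2] * lever[3] - a[3] * lever[2],
              a[3] * lever[1] - a[1] * lever[3],
              a[1] * lever[2] - a[2] * lever[1])
          }
        }
      }
      if (lam > 0)
        J[3L * nm + seq_along(par), ] <- diag(sl, length(par))
      J
    }
  }

  ctrl <- do.call(minpack.lm::nls.lm.control, utils::modifyList(
    list(maxiter = 200, ftol = 1e-15, ptol = 1e-12, gtol = 0),
    control %||% list()))
  fit <- minpack.lm::nls.lm(par = q_full[free], fn = make_resid(lambda),
                            jac = make_jac(lambda),
                            lower = bounds$lower[free],
                            upper = bounds$upper[free], control = ctrl)
  niter <- fit$niter
  trace <- fit$rsstrace
  if (lambda > 0) {
    # polish without the ridge from the already-selected basin
    fit <- minpack.lm::nls.lm(par = fit$par, fn = make_resid(0),
                              jac = make_jac(0),
                              lower = bounds$lower[free],
                              upper = bounds$upper[free], control = ctrl)
    niter <- niter + fit$niter
    trace <- c(trace, fit$rsstrace)
  }
  q_full[free] <- fit$par
  r <- make_resid(0)(fit$par)
  rn <- sqrt(colSums(matrix(r, 3)^2)) / sw  # unweighted per-marker norms, m
  report <- list(
    objective = sum(r^2),
    residual_norms = stats::setNames(rn, rownames(meas)),
    iterations = niter,
    objective_trace = trace,
    converged = fit$info %in% 1:4,
    info = fit$info,
    message = fit$message
  )
  list(q = q_full, report = report)
}

#' Fit the chain to a whole marker trajectory
#'
#' Runs [solve_frame()] over every frame, warm-starting frame *k* from frame
#' *k - 1*'s solution and frame 1 from the static-posture initializer. Frames
#' with fewer than three usable non-collinear markers are flagged invalid
#' (never interpolated).
#'
#' @param chain a [build_chain()] result.
#' @param markers a [marker_trajectories()].
#' @param weights named per-marker weights.
#' @param q_init optional starting vector for the first frame.
#' @param control solver control list, see [solve_frame()].
#' @return list with `q_traj` (a [q_trajectory()] with validity flags) and
#'   `reports` (per-frame solve reports).
#' @export
solve_trajectory <- function(chain, markers, weights = default_weights(chain),
                             q_init = static_posture(chain), control = NULL) {
  stopifnot(inherits(markers, "marker_trajectories"))
  nf <- n_frames(markers)
  qmat <- matrix(NA_real_, nf, chain$n_q,
                 dimnames = list(NULL, chain$q_names))
  valid <- rep(FALSE, nf)
  reports <- vector("list", nf)
  q_prev <- as.numeric(q_init)
  q_prev2 <- NULL
  warned <- FALSE
  for (f in seq_len(nf)) {
    meas <- marker_frame(markers, f)
    use <- .usable_markers(chain, meas, weights, warn = !warned)
    warned <- TRUE
    if (length(use) < 3L || .collinear(meas[use, , drop = FALSE])) {
      reports[[f]] <- list(objective = NA_real_, converged = FALSE,
                           skipped = TRUE)
      q_prev2 <- NULL  # do not extrapolate across a gap
      next
    }
    # warm start: linear extrapolation of the two previous solutions (lag
    # O(dt^2) instead of O(dt) on fast punch phases)
    q_start <- if (is.null(q_prev2)) q_prev else 2 * q_prev - q_prev2
    fit <- .lm_fit(chain, meas[use, , drop = FALSE], weights[use], q_start,
                   NULL, control)
    qmat[f, ] <- fit$q
    valid[f] <- TRUE
    reports[[f]] <- fit$report
    q_prev2 <- if (f > 1L && valid[f]) q_prev else NULL
    q_prev <- fit$q
  }
  list(q_traj = q_trajectory(qmat, markers$rate, markers$start_time, valid),
       reports = reports)
}

#' Select a weight scheme by residual analysis
#'
#' Solves a calibration trial under each candidate scheme and returns the one
#' minimizing the mean weight-normalized residual RMS (so that rescaling all
#' weights of a scheme does not change its score). Ties go to the first
#' candidate.
#'
#' @param chain a [build_chain()] result.
#' @param markers calibration [marker_trajectories()].
#' @param candidates non-empty list of named per-marker weight vectors.
#' @param control solver control list.
#' @return the winning element of `candidates`, with attribute `"scores"`.
#' @export
tune_weights <- function(chain, markers, candidates, control = NULL) {
  if (length(candidates) < 1L)
    stop("need at least one candidate weight scheme", call. = FALSE)
  scores <- vapply(candidates, function(w) {
    sol <- solve_trajectory(chain, markers, weights = w, control = control)
    obj <- vapply(sol$reports, function(r) r$objective %||% NA_real_,
                  numeric(1))
    sqrt(mean(obj[sol$q_traj$valid] / sum(w), na.rm = TRUE))
  }, numeric(1))
  # schemes within 1e-9 m RMS (sub-nanometer) are ties: first one wins
  best <- which(scores <= min(scores) + 1e-9)[1]
  out <- candidates[[best]]
  attr(out, "scores") <- scores
  out
}

#' Export solved generalized coordinates as a segment pose stream
#'
#' Applies forward kinematics frame by frame; invalid frames carry `NA`
#' poses and keep their invalid flag.
#'
#' @param chain a [build_chain()] result.
#' @param q_traj a [q_trajectory()].
#' @return a [pose_stream()].
#' @export
export_poses <- function(chain, q_traj) {
  stopifnot(inherits(q_traj, "q_trajectory"))
  nf <- n_frames(q_traj)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    if (!q_traj$valid[f]) next
    frames[[f]] <- .fk_fast(chain, q_traj$q[f, ])
  }
  .poses_to_stream(frames, names(chain$segments), q_traj$rate,
                   q_traj$start_time, q_traj$valid)
}
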