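#' Normality check for paired differences
#'
#' Shapiro-Wilk test at the configured significance level on the pooled
#' values; samples larger than 5000 are deterministically subsampled (evenly
#' spaced indices) to stay within the test's support. A degenerate
#' (zero-variance) vector is reported as non-normal with a `degenerate`
#' attribute.
#'
#' @param x numeric vector, `n >= 8` after removing non-finite values.
#' @param alpha significance level, default 0.05.
#' @return logical: `TRUE` if normality is not rejected. Attributes
#'   `p_value` and `degenerate`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 8L)
    stop("normality check requires at least 8 finite values; got ",
         length(x), call. = FALSE)
  if (stats::sd(x) == 0) {
    out <- FALSE
    attr(out, "p_value") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (length(x) > 5000L)
    x <- x[round(seq(1L, length(x), length.out = 5000L))]
  p <- stats::shapiro.test(x)$p.value
  out <- p >= alpha
  attr(out, "p_value") <- p
  attr(out, "degenerate") <- FALSE
  out
}

#' Bland-Altman agreement between two measurement methods
#'
#' Computes the paired differences `d = test - reference` pooled across
#' trials and subjects and summarizes them as bias and confidence interval
#' with normality branching: if the differences pass the normality check the
#' bias is their mean and the CI half-width `1.96 * sd(d)`; otherwise the
#' bias is the median and the CI `1.45 * IQR(d)`. The coefficient of
#' determination (squared Pearson correlation of test vs reference) and the
#' root-mean-square difference complete the battery.
#'
#' @param reference numeric vector from the reference method (e.g.
#'   marker-based).
#' @param test numeric vector from the test method (e.g. markerless), same
#'   length.
#' @param alpha normality significance level.
#' @return object of class `agreement_result`: list with `b`, `ci`, `r2`,
#'   `rmsd`, `n`, `normal` (branch taken), `degenerate`.
#' @export
#' @examples
#' set.seed(1)
#' ref <- rnorm(500); test <- ref + rnorm(500, mean = 2, sd = 5)
#' bland_altman(ref, test)
bland_altman <- function(reference, test, alpha = 0.05) {
  stopifnot(length(reference) == length(test))
  keep <- is.finite(reference) & is.finite(test)
  reference <- reference[keep]; test <- test[keep]
  n <- length(reference)
  if (n < 3L)
    stop("need at least 3 finite pairs; got ", n, call. = FALSE)
  d <- test - reference
  if (all(d == d[1])) {
    # all-equal differences: degenerate but well-defined
    res <- list(b = d[1], ci = 0, r2 = r_squared(reference, test),
                rmsd = abs(d[1]), n = n, normal = NA, degenerate = TRUE)
    return(structure(res, class = "agreement_result"))
  }
  normal <- if (n >= 8L) as.logical(normality_check(d, alpha)) else TRUE
  if (normal) {
    b <- mean(d)
    ci <- 1.96 * stats::sd(d)
  } else {
    b <- stats::median(d)
    ci <- 1.45 * stats::IQR(d, type = 7)
  }
  structure(list(b = b, ci = ci, r2 = r_squared(reference, test),
                 rmsd = rmsd(reference, test), n = n, normal = normal,
                 degenerate = FALSE),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  br <- if (isTRUE(x$degenerate)) "degenerate" else
    if (isTRUE(x$normal)) "normal (mean, 1.96 sd)" else
      "non-normal (median, 1.45 IQR)"
  cat(sprintf("<agreement> b = %.3g, CI = %.3g, R2 = %.3g, RMSD = %.3g, n = %d [%s]\n",
              x$b, x$ci, if (is.na(x$r2)) NA else x$r2, x$rmsd, x$n, br))
  invisible(x)
}

#' Root-mean-square difference between paired series
#' @param reference,test numeric vectors of equal length.
#' @return `sqrt(mean((test - reference)^2))` over finite pairs.
#' @export
rmsd <- function(reference, test) {
  stopifnot(length(reference) == length(test))
  keep <- is.finite(reference) & is.finite(test)
  sqrt(mean((test[keep] - reference[keep])^2))
}

#' Squared Pearson correlation between paired series
#'
#' The association measure paired with the Bland-Altman battery. Note it is
#' insensitive to constant offsets and scale (a pure offset still gives
#' `r2 = 1`), which is why it complements rather than replaces the bias.
#'
#' @param reference,test numeric vectors of equal length.
#' @return squared correlation, or `NA` (with a warning) if the reference
#'   variance is zero.
#' @export
r_squared <- function(reference, test) {
  stopifnot(length(reference) == length(test))
  keep <- is.finite(reference) & is.finite(test)
  r <- reference[keep]; t_ <- test[keep]
  if (stats::sd(r) == 0 || stats::sd(t_) == 0) {
    warning("zero-variance series: R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(r, t_)^2
}

#' Median (IQR) joint-center distance summary
#'
#' Pools the per-frame 3D joint-center distances across trials and subjects
#' and reports median and interquartile range per joint and side, in
#' centimeters (linear-interpolation quantiles, type 7).
#'
#' @param distances tibble from [joint_center_distance()] (or several
#'   row-bound together), columns `joint`, `side`, `distance_m`.
#' @return tibble with columns `joint`, `side`, `median_cm`, `iqr_cm`, `n`.
#' @export
summarize_distances <- function(distances) {
  stopifnot(all(c("joint", "side", "distance_m") %in% names(distances)))
  groups <- unique(distances[, c("joint", "side")])
  rows <- vector("list", 0)
  for (g in seq_len(nrow(groups))) {
    sel <- distances$joint == groups$joint[g] &
      distances$side == groups$side[g]
    d <- distances$distance_m[sel]
    d <- d[is.finite(d)]
    if (length(d) < 3L) {
      warning("joint ", groups$joint[g], " (", groups$side[g],
              ") has fewer than 3 samples; omitted", call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      joint = groups$joint[g], side = groups$side[g],
      median_cm = stats::median(d) * 100,
      iqr_cm = stats::IQR(d, type = 7) * 100, n = length(d))
  }
  if (!length(rows))
    return(tibble::tibble(joint = character(), side = character(),
                          median_cm = numeric(), iqr_cm = numeric(),
                          n = integer()))
  do.call(rbind, rows)
}

#' Assemble the full agreement report
#'
#' Produces the three study tables: per-joint/per-axis angle agreement and
#' per-segment velocity agreement (columns `b`, `ci`, `r2`, `rmsd`), plus the
#' joint-center distance summary. Locked model axes (elbow
#' abduction/adduction, wrist internal/external rotation) are absent from the
#' angle table. Variables whose paired series is empty are omitted with a
#' warning.
#'
#' @param angles_ref,angles_test joint-angle tibbles from [joint_angles()]
#'   on the reference and test streams (equal frame grids); several trials
#'   may be row-bound, pooled before statistics.
#' @param speeds_ref,speeds_test segment-speed tibbles from [com_speed()].
#' @param distances tibble from [joint_center_distance()].
#' @param alpha normality significance level.
#' @return object of class `agreement_report`: list of tibbles `angles`
#'   (joint, side, axis, b, ci, r2, rmsd, n, normal), `velocities` (segment,
#'   side, ...), `joint_centers` (from [summarize_distances()]). Angle
#'   statistics in degrees, velocities in m/s, distances in cm.
#' @export
build_report <- function(angles_ref, angles_test, speeds_ref, speeds_test,
                         distances, alpha = 0.05) {
  angle_rows <- .paired_table(angles_ref, angles_test,
                              c("joint", "side", "axis"), "value_deg", alpha)
  vel_rows <- .paired_table(speeds_ref, speeds_test,
                            c("segment", "side"), "speed_mps", alpha)
  structure(list(angles = angle_rows, velocities = vel_rows,
                 joint_centers = summarize_distances(distances)),
            class = "agreement_report")
}

.paired_table <- function(ref, test, keys, value, alpha) {
  stopifnot(identical(nrow(ref), nrow(test)))
  groups <- unique(ref[, keys])
  rows <- vector("list", 0)
  for (g in seq_len(nrow(groups))) {
    sel_r <- rep(TRUE, nrow(ref)); sel_t <- rep(TRUE, nrow(test))
    for (k in keys) {
      sel_r <- sel_r & ref[[k]] == groups[[k]][g]
      sel_t <- sel_t & test[[k]] == groups[[k]][g]
    }
    x_r <- ref[[value]][sel_r]; x_t <- test[[value]][sel_t]
    keep <- is.finite(x_r) & is.finite(x_t)
    if (all(is.na(x_r)) && all(is.na(x_t))) next  # locked axis: row absent
    if (sum(keep) < 3L) {
      warning("variable ", paste(unlist(groups[g, ]), collapse = "/"),
              " has fewer than 3 finite pairs; omitted", call. = FALSE)
      next
    }
    ba <- bland_altman(x_r[keep], x_t[keep], alpha)
    row <- groups[g, ]
    row$b <- ba$b; row$ci <- ba$ci; row$r2 <- ba$r2; row$rmsd <- ba$rmsd
    row$n <- ba$n; row$normal <- ba$normal
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    empty <- unique(ref[0, keys])
    empty$b <- numeric(0); empty$ci <- numeric(0); empty$r2 <- numeric(0)
    empty$rmsd <- numeric(0); empty$n <- integer(0); empty$normal <- logical(0)
    return(tibble::as_tibble(empty))
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n\nJoint angles (deg):\n")
  print(as.data.frame(x$angles), digits = 3)
  cat("\nSegment velocity magnitudes (m/s):\n")
  print(as.data.frame(x$velocities), digits = 3)
  cat("\nJoint-center distances (cm):\n")
  print(as.data.frame(x$joint_centers), digits = 3)
  invisible(x)
}

#' Write an agreement report to disk
#'
#' Writes the three tables as CSV files (`angles.csv`, `velocities.csv`,
#' `joint_centers.csv`) plus a machine-readable JSON variant
#' (`report.json`), and returns the file paths.
#'
#' @param report an [build_report()] result.
#' @param dir output directory (created if missing).
#' @param meta optional named list stamped into the JSON (e.g. config hash,
#'   seed, package version).
#' @return invisibly, the named vector of written paths.
#' @export
write_report <- function(report, dir, meta = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(angles = file.path(dir, "angles.csv"),
             velocities = file.path(dir, "velocities.csv"),
             joint_centers = file.path(dir, "joint_centers.csv"),
             json = file.path(dir, "report.json"))
  utils::write.csv(report$angles, paths["angles"], row.names = FALSE)
  utils::write.csv(report$velocities, paths["velocities"], row.names = FALSE)
  utils::write.csv(report$joint_centers, paths["joint_centers"],
                   row.names = FALSE)
  payload <- list(angles = report$angles, velocities = report$velocities,
                  joint_centers = report$joint_centers,
                  meta = meta %||% list(package = "boxkin",
                                        version = as.character(utils::packageVersion("boxkin"))))
  jsonlite::write_json(payload, paths["json"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
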