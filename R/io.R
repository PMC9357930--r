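# ---- TRC ------------------------------------------------------------------

#' Write marker trajectories as a TRC file
#'
#' Standard tab-separated TRC layout (header with rates, frame and marker
#' counts, units; one row per frame with X/Y/Z triplets per marker).
#' Coordinates are written in the requested units.
#'
#' @param markers a [marker_trajectories()].
#' @param path output file path.
#' @param units `"m"` or `"mm"`.
#' @return invisibly, `path`.
#' @export
write_trc <- function(markers, path, units = "m") {
  stopifnot(inherits(markers, "marker_trajectories"), units %in% c("m", "mm"))
  fac <- if (units == "mm") 1000 else 1
  labs <- marker_labels(markers)
  nf <- n_frames(markers)
  tt <- time_axis(markers)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("PathFileType\t4\t(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(markers$rate, markers$rate, nf, length(labs), units, markers$rate,
          1, nf, sep = "\t"),
    paste(c("Frame#", "Time", unlist(lapply(labs, function(l) c(l, "", "")))),
          collapse = "\t"),
    paste(c("", "", unlist(lapply(seq_along(labs), function(i)
      paste0(c("X", "Y", "Z"), i)))), collapse = "\t")
  ), con)
  flat <- matrix(aperm(markers$pos, c(3, 2, 1)), nrow = nf, byrow = TRUE) * fac
  rows <- vapply(seq_len(nf), function(f) {
    paste(c(f, format(tt[f], digits = 10),
            format(flat[f, ], digits = 10)), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Read a TRC marker file
#'
#' @param path TRC file path.
#' @return a [marker_trajectories()] in meters (mm files are converted).
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5L)
    stop("'", path, "': not a TRC file (fewer than 5 header lines)",
         call. = FALSE)
  hdr <- strsplit(lines[3], "\t")[[1]]
  rate <- as.numeric(hdr[1])
  nm <- as.integer(hdr[4])
  units <- hdr[5]
  if (!is.finite(rate) || rate <= 0)
    stop("'", path, "': invalid DataRate", call. = FALSE)
  labs <- strsplit(lines[4], "\t")[[1]]
  labs <- labs[labs != ""][-(1:2)]
  if (length(labs) != nm)
    stop("'", path, "': header announces ", nm, " markers but lists ",
         length(labs), " labels", call. = FALSE)
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  nf <- length(body)
  pos <- array(NA_real_, c(nf, nm, 3),
               dimnames = list(NULL, labs, c("x", "y", "z")))
  start_time <- 0
  for (f in seq_len(nf)) {
    v <- suppressWarnings(as.numeric(strsplit(body[f], "\t")[[1]]))
    if (f == 1L) start_time <- v[2]
    coords <- v[3:(2 + 3 * nm)]
    pos[f, , ] <- matrix(coords, nm, 3, byrow = TRUE)
  }
  fac <- if (identical(tolower(units), "mm")) 1 / 1000 else 1
  marker_trajectories(pos * fac, rate, start_time)
}

# ---- Pose-stream CSV ------------------------------------------------------

#' Write a pose stream as CSV
#'
#' One row per frame and segment with columns `frame`, `time_s`, `segment`,
#' `r11..r33` (rotation, row-major) and `tx, ty, tz` (meters). Invalid
#' frames are written with empty pose fields.
#'
#' @param stream a [pose_stream()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_poses <- function(stream, path) {
  stopifnot(inherits(stream, "pose_stream"))
  nf <- n_frames(stream)
  tt <- time_axis(stream)
  segs <- stream$segments
  n <- nf * length(segs)
  df <- data.frame(frame = rep(seq_len(nf) - 1L, each = length(segs)),
                   time_s = rep(tt, each = length(segs)),
                   segment = rep(segs, nf))
  rot_cols <- as.vector(t(outer(1:3, 1:3, function(i, j)
    paste0("r", i, j))))
  m <- matrix(NA_real_, n, 12)
  k <- 0L
  for (f in seq_len(nf)) for (s in segs) {
    k <- k + 1L
    Tm <- stream$T[, , s, f]
    m[k, ] <- c(t(Tm[1:3, 1:3]), Tm[1:3, 4])
  }
  colnames(m) <- c(rot_cols, "tx", "ty", "tz")
  utils::write.csv(cbind(df, as.data.frame(m)), path, row.names = FALSE)
  invisible(path)
}

#' Read a pose-stream CSV
#'
#' Validates that every stored rotation is orthonormal with determinant +1
#' within `tol`; a violating row is rejected with its frame index. Rows with
#' missing pose fields become invalid frames.
#'
#' @param path CSV path in the [write_poses()] dialect.
#' @param rate sampling rate in Hz; if `NULL`, inferred from the `time_s`
#'   column.
#' @param tol orthonormality tolerance (default 1e-6).
#' @return a [pose_stream()].
#' @export
read_poses <- function(path, rate = NULL, tol = 1e-6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "segment",
            as.vector(t(outer(1:3, 1:3, function(i, j) paste0("r", i, j)))),
            "tx", "ty", "tz")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("'", path, "': missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  segs <- unique(df$segment)
  frames <- sort(unique(df$frame))
  nf <- length(frames)
  if (nf == 0L) {
    T <- array(NA_real_, c(4, 4, length(segs), 0),
               dimnames = list(NULL, NULL, segs, NULL))
    return(pose_stream(T, rate %||% 1))
  }
  if (is.null(rate)) {
    tt <- sort(unique(df$time_s))
    rate <- if (length(tt) > 1L) 1 / stats::median(diff(tt)) else 1
  }
  T <- array(NA_real_, c(4, 4, length(segs), nf),
             dimnames = list(NULL, NULL, segs, NULL))
  valid <- rep(TRUE, nf)
  fidx <- match(df$frame, frames)
  sidx <- match(df$segment, segs)
  rot_cols <- as.vector(t(outer(1:3, 1:3, function(i, j) paste0("r", i, j))))
  for (k in seq_len(nrow(df))) {
    vals <- as.numeric(df[k, c(rot_cols, "tx", "ty", "tz")])
    f <- fidx[k]
    if (any(!is.finite(vals))) {
      valid[f] <- FALSE
      next
    }
    R <- matrix(vals[1:9], 3, 3, byrow = TRUE)
    if (!is_rotation(R, tol))
      stop("'", path, "': non-orthonormal rotation at frame ", df$frame[k],
           ", segment ", df$segment[k], call. = FALSE)
    T[, , sidx[k], f] <- rbind(cbind(R, vals[10:12]), c(0, 0, 0, 1))
  }
  pose_stream(T, rate, start_time = min(df$time_s), valid = valid)
}

# ---- Chain YAML -----------------------------------------------------------

#' Serialize a kinematic chain to YAML
#'
#' Writes the full chain geometry (profile, segment lengths and offsets,
#' joint DoF masks, marker map, joint-center local points, landmark pairs) so
#' that a scaled, subject-specific chain can be reloaded exactly.
#'
#' @param chain a [build_chain()] result.
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_chain <- function(chain, path) {
  doc <- list(
    profile = unclass(chain$profile),
    lengths = as.list(chain$lengths),
    com_frac = as.list(chain$com_frac),
    segments = lapply(chain$segments, function(s)
      list(offset = as.numeric(s$offset), length = s$length,
           com = as.numeric(s$com))),
    joints = lapply(chain$joints, function(j)
      list(type = j$type, segment = j$segment,
           free_rotations = as.list(j$free_rotations),
           free_translations = as.list(j$free_translations))),
    markers = lapply(chain$markers, function(m)
      list(segment = m$segment, local = as.numeric(m$local))),
    joint_local = lapply(chain$joint_local, function(j)
      list(segment = j$segment, point = as.numeric(j$point))),
    landmark_pairs = lapply(chain$landmark_pairs, as.list)
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a kinematic chain from YAML
#' @param path YAML path written by [write_chain()].
#' @return a `kinematic_chain`.
#' @export
read_chain <- function(path) {
  doc <- yaml::read_yaml(path)
  profile <- anthro_profile(doc$profile$sex, doc$profile$height,
                            doc$profile$mass)
  geometry <- list(
    segments = lapply(doc$segments, function(s)
      list(offset = as.numeric(s$offset), length = s$length,
           com = as.numeric(s$com))),
    markers = lapply(doc$markers, function(m)
      list(segment = m$segment, local = as.numeric(m$local))),
    joint_local = lapply(doc$joint_local, function(j)
      list(segment = j$segment, point = as.numeric(j$point))),
    landmark_pairs = lapply(doc$landmark_pairs, function(p)
      as.character(unlist(p)))
  )
  .new_chain(profile, unlist(doc$lengths), unlist(doc$com_frac), geometry)
}

# ---- C3D ------------------------------------------------------------------
# Minimal C3D implementation (Intel processor type, floating-point data,
# POINT group with USED/FRAMES/RATE/SCALE/DATA_START/LABELS/UNITS). Covers
# round-tripping labeled point data; written files follow the published
# block/parameter layout.

.c3d_pad_block <- function(r) {
  pad <- (-length(r)) %% 512L
  c(r, raw(pad))
}

.c3d_param_record <- function(name, group_id, type = NULL, dims = NULL,
                              data = NULL, is_group = FALSE, last = FALSE) {
  name_raw <- charToRaw(name)
  body <- raw(0)
  if (is_group) {
    body <- as.raw(0L)  # description length 0
  } else {
    body <- c(writeBin(as.integer(type), raw(), size = 1L),
              as.raw(length(dims)),
              as.raw(as.integer(dims)),
              data,
              as.raw(0L))  # description length 0
  }
  offset <- if (last) 0L else length(body) + 2L
  c(writeBin(length(name_raw), raw(), size = 1L),
    writeBin(as.integer(group_id), raw(), size = 1L),
    name_raw,
    writeBin(as.integer(offset), raw(), size = 2L, endian = "little"),
    body)
}

#' Write marker trajectories as a C3D file
#'
#' Writes a floating-point, little-endian C3D with a POINT parameter group
#' (USED, FRAMES, RATE, SCALE, DATA_START, LABELS, UNITS). Coordinates are
#' stored in the requested units.
#'
#' @param markers a [marker_trajectories()].
#' @param path output path.
#' @param units `"m"` or `"mm"`.
#' @return invisibly, `path`.
#' @export
write_c3d <- function(markers, path, units = "m") {
  stopifnot(inherits(markers, "marker_trajectories"), units %in% c("m", "mm"))
  labs <- marker_labels(markers)
  if (length(labs) == 0L)
    stop("cannot write a C3D without markers", call. = FALSE)
  nf <- n_frames(markers)
  nm <- length(labs)
  fac <- if (units == "mm") 1000 else 1
  lab_w <- max(4L, max(nchar(labs)))
  labs_pad <- formatC(labs, width = -lab_w)

  i16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                              endian = "little")
  f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4L,
                              endian = "little")

  params <- c(
    .c3d_param_record("POINT", -1L, is_group = TRUE),
    .c3d_param_record("USED", 1L, type = 2L, dims = integer(0),
                      data = i16(nm)),
    .c3d_param_record("FRAMES", 1L, type = 2L, dims = integer(0),
                      data = i16(min(nf, 32767L))),
    .c3d_param_record("RATE", 1L, type = 4L, dims = integer(0),
                      data = f32(markers$rate)),
    .c3d_param_record("SCALE", 1L, type = 4L, dims = integer(0),
                      data = f32(-1)),
    .c3d_param_record("UNITS", 1L, type = -1L, dims = 4L,
                      data = charToRaw(formatC(units, width = -4L))),
    .c3d_param_record("LABELS", 1L, type = -1L, dims = c(lab_w, nm),
                      data = charToRaw(paste(labs_pad, collapse = "")))
  )
  n_param_blocks <- ceiling((4L + length(params)) / 512L)
  data_start <- 2L + n_param_blocks

  # DATA_START must be known before finalizing the parameter section; append
  # it and recompute the block count (stable for our small parameter sets).
  params <- c(params,
              .c3d_param_record("DATA_START", 1L, type = 2L,
                                dims = integer(0), data = i16(data_start),
                                last = TRUE))
  n_param_blocks2 <- ceiling((4L + length(params)) / 512L)
  if (n_param_blocks2 != n_param_blocks) {
    data_start <- 2L + n_param_blocks2
    # patch the two data bytes of DATA_START (last record: ..., lo, hi, desc)
    params[length(params) - c(2L, 1L)] <- i16(data_start)
  }
  param_header <- c(as.raw(c(0x01, 0x50)),
                    as.raw(n_param_blocks2),
                    as.raw(84L))  # 84 = Intel

  header <- c(as.raw(c(0x02, 0x50)),      # parameter block pointer, magic
              i16(nm), i16(0L),           # points, analog
              i16(1L), i16(min(nf, 32767L)),
              i16(0L),                    # max interpolation gap
              f32(-1),                    # scale (negative = float)
              i16(data_start),
              i16(0L),                    # analog samples per frame
              f32(markers$rate))
  header <- .c3d_pad_block(header)
  param_sec <- .c3d_pad_block(c(param_header, params))

  dat <- array(aperm(markers$pos, c(3, 2, 1)), dim = c(3, nm, nf)) * fac
  block <- array(0, dim = c(4, nm, nf))
  block[1:3, , ] <- dat
  data_sec <- .c3d_pad_block(f32(as.numeric(block)))

  writeBin(c(header, param_sec, data_sec), path)
  invisible(path)
}

#' Read a C3D marker file
#'
#' Parses the parameter section generically and extracts the POINT group.
#' Both floating-point and scaled-integer data are supported; coordinates
#' are normalized to meters using the POINT:UNITS field.
#'
#' @param path C3D path.
#' @return a [marker_trajectories()] in meters.
#' @export
read_c3d <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 512L || raw_all[2] != as.raw(0x50))
    stop("'", path, "': not a C3D file (bad magic byte)", call. = FALSE)
  rd_i16 <- function(off, n = 1L)
    readBin(raw_all[(off + 1):(off + 2 * n)], "integer", n = n, size = 2L,
            endian = "little")
  rd_f32 <- function(off, n = 1L)
    readBin(raw_all[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4L,
            endian = "little")
  param_block <- as.integer(raw_all[1])
  n_points <- rd_i16(2)
  first_frame <- rd_i16(6)
  last_frame <- rd_i16(8)
  hdr_scale <- rd_f32(12)
  hdr_data_start <- rd_i16(16)
  hdr_rate <- rd_f32(20)

  poff <- (param_block - 1L) * 512L
  # parse parameter records
  params <- list()
  groups <- character(0)
  cur <- poff + 4L
  repeat {
    nlen <- readBin(raw_all[cur + 1], "integer", size = 1L, signed = TRUE)
    gid <- readBin(raw_all[cur + 2], "integer", size = 1L, signed = TRUE)
    if (nlen == 0L || gid == 0L) break
    locked <- nlen < 0L
    nlen <- abs(nlen)
    name <- rawToChar(raw_all[(cur + 3):(cur + 2 + nlen)])
    off_field <- cur + 2L + nlen
    nxt <- rd_i16(off_field)
    body <- off_field + 2L
    if (gid < 0L) {
      groups[as.character(-gid)] <- name
    } else {
      type <- readBin(raw_all[body + 1], "integer", size = 1L, signed = TRUE)
      ndim <- as.integer(raw_all[body + 2])
      dims <- if (ndim > 0)
        as.integer(raw_all[(body + 3):(body + 2 + ndim)]) else integer(0)
      count <- prod(c(1L, dims))
      doff <- body + 2L + ndim
      value <- switch(as.character(type),
        "-1" = rawToChar(raw_all[(doff + 1):(doff + count)]),
        "1" = as.integer(raw_all[(doff + 1):(doff + count)]),
        "2" = rd_i16(doff, count),
        "4" = rd_f32(doff, count),
        stop("'", path, "': unknown parameter type ", type, call. = FALSE))
      params[[paste0(gid, ":", name)]] <- list(value = value, dims = dims)
    }
    if (nxt == 0L) break
    cur <- off_field + nxt
  }
  point_gid <- names(groups)[groups == "POINT"]
  if (length(point_gid) != 1L)
    stop("'", path, "': missing POINT parameter group", call. = FALSE)
  getp <- function(name, default = NULL) {
    p <- params[[paste0(point_gid, ":", name)]]
    if (is.null(p)) default else p
  }
  used <- getp("USED")$value %||% n_points
  if (is.null(used) || used == 0L)
    stop("'", path, "': C3D contains no points", call. = FALSE)
  rate <- getp("RATE")$value %||% hdr_rate
  scale <- getp("SCALE")$value %||% hdr_scale
  data_start <- getp("DATA_START")$value %||% hdr_data_start
  units <- trimws(getp("UNITS")$value %||% "m")
  labp <- getp("LABELS")
  labs <- if (!is.null(labp)) {
    w <- labp$dims[1]
    trimws(substring(labp$value, seq(1, by = w, length.out = labp$dims[2]),
                     seq(w, by = w, length.out = labp$dims[2])))
  } else paste0("M", seq_len(used))
  nf <- last_frame - first_frame + 1L
  framep <- getp("FRAMES")
  if (!is.null(framep)) nf <- max(nf, framep$value)

  doff <- (data_start - 1L) * 512L
  if (scale < 0) {
    vals <- rd_f32(doff, 4L * used * nf)
    arr <- array(vals, dim = c(4, used, nf))
    coords <- arr[1:3, , , drop = FALSE]
  } else {
    vals <- rd_i16(doff, 4L * used * nf)
    arr <- array(vals, dim = c(4, used, nf))
    coords <- arr[1:3, , , drop = FALSE] * scale
  }
  pos <- aperm(coords, c(3, 2, 1))
  dimnames(pos) <- list(NULL, labs[seq_len(used)], c("x", "y", "z"))
  fac <- if (identical(tolower(units), "mm")) 1 / 1000 else 1
  marker_trajectories(pos * fac, rate)
}

# ---- Run configuration ----------------------------------------------------

#' Read a pipeline run configuration
#'
#' Parses the YAML configuration consumed by [run_study()] and the command
#' line interface: anthropometric profile, punch script, corruption model,
#' markerless-system emulation (angle biases in degrees, joint-center
#' offsets in centimeters), filter specification, marker weights, lead side
#' and seed.
#'
#' @param path YAML path.
#' @return a named list of constructed component objects plus scalars,
#'   including a short content `hash` used to stamp output artifacts.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  profile <- do.call(anthro_profile, doc$profile)
  script <- do.call(punch_script, doc$script %||% list())
  corr <- do.call(corruption_model, doc$corruption %||% list())
  emu_cfg <- doc$emulation %||% list()
  angle_bias <- numeric(0)
  if (!is.null(emu_cfg$angle_bias_deg))
    angle_bias <- unlist(emu_cfg$angle_bias_deg) * pi / 180
  center_offset <- list()
  if (!is.null(emu_cfg$center_offset_cm))
    center_offset <- lapply(emu_cfg$center_offset_cm,
                            function(v) as.numeric(v) / 100)
  emu <- system_emulation(
    angle_bias = angle_bias,
    pose_noise_sd_rad = (emu_cfg$pose_noise_sd_deg %||% 0) * pi / 180,
    pose_noise_sd_m = emu_cfg$pose_noise_sd_m %||% 0,
    rate = emu_cfg$rate %||% 60,
    center_offset = center_offset)
  fspec <- do.call(filter_spec, doc$filter %||% list())
  list(profile = profile, script = script, corruption = corr,
       emulation = emu, filter = fspec,
       weights = doc$weights %||% NULL,
       cardan_sequence = doc$cardan_sequence %||% "zxy",
       front_side = doc$front_side %||% "L",
       marker_rate = doc$marker_rate %||% 300,
       seed = doc$seed %||% 1,
       out_dir = doc$out_dir %||% "boxkin_out",
       hash = substr(jsonlite::base64_enc(serialize(doc, NULL)), 1, 16))
}
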