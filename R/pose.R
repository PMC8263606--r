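#' Subject metadata
#'
#' @param subject_id Character label.
#' @param height Body height in meters; must lie in (0.5, 2.6).
#' @param age,sex Optional.
#' @return A list of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, height, age = NULL, sex = NULL) {
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height <= 0.5 || height >= 2.6)
    stop("subject height must be in (0.5, 2.6) m")
  structure(list(subject_id = as.character(subject_id), height = height,
                 age = age, sex = sex), class = "subject_meta")
}

#' Pose sequence container
#'
#' The universal currency of the pipeline: a time-ordered sequence of skeleton
#' frames at a fixed frame rate, holding 2D pixel-space keypoints and/or 3D
#' metric keypoints for the canonical 21-joint topology. Frames are 0-based in
#' time: frame `i` is at `t = i / fps` seconds. Missing joints are `NA`.
#'
#' @param frames3d `NULL` or a numeric array `n_frames x 21 x 3` (x lateral m,
#'   y vertical-up m, z depth m), with joint dimnames in canonical order.
#' @param frames2d `NULL` or a numeric array `n_frames x 21 x 2` (u, v pixels;
#'   v grows downward, image convention).
#' @param fps Frames per second (> 0).
#' @param subject A [subject_meta()].
#' @param topology Skeleton topology.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(frames3d = NULL, frames2d = NULL, fps, subject,
                          topology = default_topology()) {
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  if (is.null(frames3d) && is.null(frames2d))
    stop("no frames: at least one of frames3d/frames2d must be given")
  nj <- length(topology$joints)
  chk <- function(a, d, what) {
    if (is.null(a)) return(NULL)
    if (!is.array(a) || length(dim(a)) != 3L || dim(a)[2] != nj || dim(a)[3] != d)
      stop(what, " must be an array n_frames x ", nj, " x ", d)
    if (dim(a)[1] == 0L) stop("no frames in ", what)
    dimnames(a) <- list(NULL, topology$joints,
                        if (d == 3L) c("x", "y", "z") else c("u", "v"))
    a
  }
  frames3d <- chk(frames3d, 3L, "frames3d")
  frames2d <- chk(frames2d, 2L, "frames2d")
  if (!is.null(frames3d) && !is.null(frames2d) &&
      dim(frames3d)[1] != dim(frames2d)[1])
    stop("frames2d and frames3d must have equal length when both present")
  if (!inherits(subject, "subject_meta")) stop("subject must be a subject_meta")
  structure(list(frames3d = frames3d, frames2d = frames2d, fps = fps,
                 subject = subject, topology = topology),
            class = "pose_sequence")
}

#' Number of frames of a pose sequence
#' @param seq A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) {
  a <- if (!is.null(seq$frames3d)) seq$frames3d else seq$frames2d
  dim(a)[1]
}

#' Frame timestamps of a pose sequence
#' @param seq A `pose_sequence`.
#' @return Numeric vector `(0:(n-1)) / fps` in seconds.
#' @export
frame_times <- function(seq) (seq_len(n_frames(seq)) - 1L) / seq$fps

#' Extract one joint's 3D trajectory
#' @param seq A `pose_sequence` with `frames3d`.
#' @param joint Canonical joint name.
#' @return `n_frames x 3` matrix.
#' @export
joint_track <- function(seq, joint) {
  stopifnot(!is.null(seq$frames3d))
  seq$frames3d[, joint, , drop = TRUE]
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames @ %.6g fps (%.2f s), subject %s (%.2f m)\n",
              n_frames(x), x$fps, n_frames(x) / x$fps,
              x$subject$subject_id, x$subject$height))
  cat(sprintf("  frames2d: %s  frames3d: %s\n",
              if (is.null(x$frames2d)) "absent" else "present",
              if (is.null(x$frames3d)) "absent" else "present"))
  invisible(x)
}

#' Validate a pose sequence
#'
#' Reports (rather than raises) invariant violations: non-positive fps,
#' non-finite coordinates mixed with finite ones in a joint entry, 2D/3D frame
#' count mismatch, and 3D frames where an ankle sits above the neck.
#'
#' @param seq A `pose_sequence`.
#' @return A data.frame with columns `frame`, `joint`, `issue`; zero rows iff
#'   all checked invariants hold.
#' @export
validate_sequence <- function(seq) {
  issues <- list()
  add <- function(frame, joint, issue)
    issues[[length(issues) + 1L]] <<- data.frame(
      frame = frame, joint = joint, issue = issue, stringsAsFactors = FALSE)
  if (!is.numeric(seq$fps) || seq$fps <= 0 || !is.finite(seq$fps))
    add(NA_integer_, NA_character_, "fps must be positive and finite")
  if (!is.null(seq$frames2d) && !is.null(seq$frames3d) &&
      dim(seq$frames2d)[1] != dim(seq$frames3d)[1])
    add(NA_integer_, NA_character_, "frames2d/frames3d length mismatch")
  scan <- function(a, d) {
    if (is.null(a)) return()
    fin <- is.finite(a)
    # a joint is "present" if any coordinate is finite; then all must be
    pres <- apply(fin, c(1, 2), any)
    full <- apply(fin, c(1, 2), all)
    bad <- which(pres & !full, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      for (r in seq_len(nrow(bad)))
        add(bad[r, 1] - 1L, dimnames(a)[[2]][bad[r, 2]],
            "non-finite coordinate in present joint")
  }
  scan(seq$frames2d, 2L)
  scan(seq$frames3d, 3L)
  if (!is.null(seq$frames3d)) {
    y <- seq$frames3d[, , "y", drop = FALSE]
    neck <- y[, "Neck", 1]
    for (ank in c("LAnkle", "RAnkle")) {
      a <- y[, ank, 1]
      bad <- which(is.finite(a) & is.finite(neck) & a > neck)
      for (f in bad) add(f - 1L, ank, "ankle above neck")
    }
  }
  if (length(issues) == 0L)
    data.frame(frame = integer(), joint = character(), issue = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, issues)
}

# ---- JSON I/O --------------------------------------------------------------

#' Read a pose sequence from JSON
#'
#' The on-disk format mirrors the per-frame joint lists emitted by 2D/3D pose
#' detectors: `{"meta": {"fps": .., "height_m": .., "subject_id": ".."},
#' "frames": [{"joints2d": {name: {"x":u,"y":v}}, "joints3d":
#' {name: {"x":..,"y":..,"z":..}}}]}`. Joint names are mapped through
#' [joint_aliases()]; unknown names are rejected with the frame index.
#'
#' @param path File path.
#' @param dialect One of `"pose-json-2d"`, `"pose-json-3d"`,
#'   `"pose-json-combined"`; declares which channels must be present.
#' @param topology Skeleton topology.
#' @return A [pose_sequence()].
#' @export
read_pose_sequence <- function(path, dialect = "pose-json-combined",
                               topology = default_topology()) {
  dialect <- match.arg(dialect,
                       c("pose-json-2d", "pose-json-3d", "pose-json-combined"))
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  meta <- doc$meta
  if (is.null(meta$fps) || is.null(meta$height_m))
    stop("configuration error: pose file meta must provide fps and height_m")
  frames <- doc$frames
  if (is.null(frames) || length(frames) == 0L) stop("no frames in ", path)
  n <- length(frames)
  nj <- length(topology$joints)
  al <- joint_aliases()
  want2d <- dialect %in% c("pose-json-2d", "pose-json-combined")
  want3d <- dialect %in% c("pose-json-3d", "pose-json-combined")
  a2 <- array(NA_real_, c(n, nj, 2), dimnames = list(NULL, topology$joints, c("u", "v")))
  a3 <- array(NA_real_, c(n, nj, 3), dimnames = list(NULL, topology$joints, c("x", "y", "z")))
  has2 <- FALSE; has3 <- FALSE
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    j2 <- fr$joints2d
    if (!is.null(j2) && length(j2) > 0L) {
      has2 <- TRUE
      for (nm in names(j2)) {
        can <- unname(al[nm])
        if (is.na(can))
          stop("parse error at frame ", i - 1L, ": unknown joint '", nm, "'")
        pt <- j2[[nm]]
        if (!is.numeric(pt$x) || !is.numeric(pt$y))
          stop("parse error at frame ", i - 1L, ", joint '", nm,
               "': malformed 2D record")
        a2[i, can, ] <- c(pt$x, pt$y)
      }
    }
    j3 <- fr$joints3d
    if (!is.null(j3) && length(j3) > 0L) {
      has3 <- TRUE
      for (nm in names(j3)) {
        can <- unname(al[nm])
        if (is.na(can))
          stop("parse error at frame ", i - 1L, ": unknown joint '", nm, "'")
        pt <- j3[[nm]]
        if (!is.numeric(pt$x) || !is.numeric(pt$y) || !is.numeric(pt$z))
          stop("parse error at frame ", i - 1L, ", joint '", nm,
               "': malformed 3D record")
        a3[i, can, ] <- c(pt$x, pt$y, pt$z)
      }
    }
  }
  if (want2d && !has2) stop("dialect ", dialect, " requires joints2d")
  if (want3d && !has3) stop("dialect ", dialect, " requires joints3d")
  pose_sequence(frames3d = if (has3) a3 else NULL,
                frames2d = if (has2) a2 else NULL,
                fps = meta$fps,
                subject = subject_meta(meta$subject_id %||% "unknown",
                                       meta$height_m),
                topology = topology)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pose sequence to JSON
#'
#' Inverse of [read_pose_sequence()]: `read_pose_sequence(write_pose_sequence(seq))`
#' reproduces `seq` exactly (coordinates are serialized at full double
#' precision). Missing joints are omitted from the frame's joint map.
#'
#' @param seq A valid `pose_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pose_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!is.finite(seq$fps) || seq$fps <= 0) stop("refusing to write: fps must be > 0")
  n <- n_frames(seq)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- list()
    if (!is.null(seq$frames2d)) {
      m <- seq$frames2d[i, , , drop = TRUE]
      keep <- rownames(m)[apply(is.finite(m), 1, all)]
      if (length(keep) > 0L)
        fr$joints2d <- stats::setNames(
          lapply(keep, function(j) list(x = m[j, 1], y = m[j, 2])), keep)
    }
    if (!is.null(seq$frames3d)) {
      m <- seq$frames3d[i, , , drop = TRUE]
      keep <- rownames(m)[apply(is.finite(m), 1, all)]
      if (length(keep) > 0L)
        fr$joints3d <- stats::setNames(
          lapply(keep, function(j) list(x = m[j, 1], y = m[j, 2], z = m[j, 3])),
          keep)
    }
    frames[[i]] <- fr
  }
  doc <- list(meta = list(fps = seq$fps, height_m = seq$subject$height,
                          subject_id = seq$subject$subject_id),
              frames = frames)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Pose sequence as a long data frame
#'
#' One row per (frame, joint) with columns `frame`, `t_s`, `joint`, `u_px`,
#' `v_px`, `x_m`, `y_m`, `z_m`; the CSV export layout.
#'
#' @param x A `pose_sequence`.
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.pose_sequence <- function(x, ...) {
  n <- n_frames(x)
  joints <- x$topology$joints
  nj <- length(joints)
  out <- data.frame(
    frame = rep(0:(n - 1L), each = nj),
    t_s = rep(frame_times(x), each = nj),
    joint = rep(joints, times = n),
    stringsAsFactors = FALSE)
  get <- function(a, k) if (is.null(a)) NA_real_ else as.vector(t(a[, , k]))
  out$u_px <- get(x$frames2d, 1L); out$v_px <- get(x$frames2d, 2L)
  out$x_m <- get(x$frames3d, 1L); out$y_m <- get(x$frames3d, 2L)
  out$z_m <- get(x$frames3d, 3L)
  out
}
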