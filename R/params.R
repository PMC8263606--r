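#' Walking direction of a sequence
#'
#' Principal axis (least-squares line direction) of the pelvis trajectory in
#' the ground plane, oriented along the net displacement. Frame-order
#' reversal flips only the sign.
#'
#' @param seq `pose_sequence` with `frames3d` and the pelvis present in at
#'   least 2 frames.
#' @param min_displacement Net pelvis displacement (m) below which "no walk
#'   detected" is raised.
#' @return Unit length-3 vector with zero vertical component.
#' @export
walking_direction <- function(seq, min_displacement = 0.2) {
  stopifnot(!is.null(seq$frames3d))
  P <- seq$frames3d[, "Pelvis", c(1, 3), drop = TRUE]
  if (is.null(dim(P))) P <- matrix(P, 1)
  ok <- apply(is.finite(P), 1, all)
  P <- P[ok, , drop = FALSE]
  if (nrow(P) < 2L) stop("need at least 2 frames with the pelvis present")
  net <- P[nrow(P), ] - P[1, ]
  if (sqrt(sum(net^2)) < min_displacement) stop("no walk detected")
  ctr <- sweep(P, 2, colMeans(P))
  v <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  if (sum(v * net) < 0) v <- -v
  unit(c(v[1], 0, v[2]))
}

#' Per-step measurements at the honest landings
#'
#' For each step event: step length is the absolute walking-direction
#' component of the inter-ankle vector around the landing frame, and step
#' duration is the interval to the next landing. The projected definition
#' removes the lateral base-of-support component from the length. Because
#' both feet decelerate into the landing with vanishing velocity and
#' acceleration, the projected gap forms a locally cubic-flat peak; the step
#' length is read off as the fitted plateau of that peak model around the
#' refined landing time — a local trajectory fit that suppresses estimator
#' jitter without the peak-rounding bias of a global low-pass filter or the
#' droop of plain window averaging.
#'
#' @param events A `step_events` data.frame from [segment_steps()].
#' @param seq `pose_sequence` with `frames3d`.
#' @param direction Unit walking-direction vector.
#' @param window Half-width (frames) of the local fitting window; default
#'   `NULL` = 30% of the step period, clamped to 3..8 frames.
#' @return data.frame of class `step_records` with `index`, `side`, `length`
#'   (m), `duration` (s, `NA` for the last step), `landing_time` (s).
#' @export
step_metrics <- function(events, seq, direction = NULL, window = NULL) {
  if (nrow(events) == 0L) stop("no step events")
  if (is.null(direction)) direction <- walking_direction(seq)
  if (is.null(window)) {
    period <- stats::median(diff(events$landing_time))
    window <- as.integer(clamp(round(0.3 * period * seq$fps), 3, 8))
  }
  a3 <- seq$frames3d
  gap <- (a3[, "LAnkle", 1] - a3[, "RAnkle", 1]) * direction[1] +
    (a3[, "LAnkle", 2] - a3[, "RAnkle", 2]) * direction[2] +
    (a3[, "LAnkle", 3] - a3[, "RAnkle", 3]) * direction[3]
  n <- length(gap)
  period_frames <- stats::median(diff(events$landing_frame))
  len <- vapply(seq_len(nrow(events)), function(i) {
    f <- events$landing_frame[i]
    idx <- max(1L, f + 1L - window):min(n, f + 1L + window)
    abs(peak_plateau_value(abs(gap[idx]), idx - 1,
                           events$landing_time[i] * seq$fps, period_frames))
  }, numeric(1))
  out <- data.frame(index = events$index, side = events$side, length = len,
                    duration = events$interval_to_next,
                    landing_time = events$landing_time,
                    landing_frame = events$landing_frame,
                    stringsAsFactors = FALSE)
  class(out) <- c("step_records", "data.frame")
  out
}

#' Trial-level gait parameters from per-step records
#'
#' The four walkway-comparable averages: mean step time (s), cadence
#' `60 / step_time_mean` (steps/min), mean step length (cm), and gait speed
#' (m/s) measured as pelvis displacement along the walking direction between
#' the first and last landing divided by the elapsed time. A consistency
#' diagnostic reports the relative gap between that speed and
#' `step_length * cadence / 6000`.
#'
#' @param records `step_records` from [step_metrics()] (>= 2 with durations).
#' @param seq The `pose_sequence`.
#' @param events The `step_events` (for landing times).
#' @param direction Unit walking direction; default recomputed from `seq`.
#' @return A list of class `gait_parameters`: `gait_speed`, `cadence`,
#'   `step_length_mean`, `step_time_mean`, `n_steps`, `per_step`,
#'   `speed_consistency_gap`.
#' @export
summarize_gait <- function(records, seq, events, direction = NULL) {
  durs <- records$duration[is.finite(records$duration)]
  if (length(durs) < 1L || nrow(records) < 2L) stop("insufficient steps")
  if (is.null(direction)) direction <- walking_direction(seq)
  step_time_mean <- mean(durs)
  cadence <- 60 / step_time_mean
  step_length_mean <- mean(records$length) * 100
  # pelvis displacement between first and last landing, at refined times
  pel <- seq$frames3d[, "Pelvis", , drop = TRUE]
  s <- pel[, 1] * direction[1] + pel[, 2] * direction[2] + pel[, 3] * direction[3]
  tt <- frame_times(seq)
  t1 <- events$landing_time[1]; t2 <- events$landing_time[nrow(events)]
  s1 <- stats::approx(tt, s, xout = t1, rule = 2)$y
  s2 <- stats::approx(tt, s, xout = t2, rule = 2)$y
  gait_speed <- (s2 - s1) / (t2 - t1)
  alt <- step_length_mean * cadence / 6000
  structure(list(gait_speed = gait_speed, cadence = cadence,
                 step_length_mean = step_length_mean,
                 step_time_mean = step_time_mean,
                 n_steps = nrow(records), per_step = records,
                 speed_consistency_gap = abs(gait_speed - alt) /
                   max(abs(gait_speed), 1e-12)),
            class = "gait_parameters")
}

#' @export
print.gait_parameters <- function(x, ...) {
  cat(sprintf(paste0("gait parameters (%d steps):\n",
                     "  gait speed  %.3f m/s\n  cadence     %.2f steps/min\n",
                     "  step length %.2f cm\n  step time   %.3f s\n"),
              x$n_steps, x$gait_speed, x$cadence, x$step_length_mean,
              x$step_time_mean))
  invisible(x)
}

#' Run the full analysis on a 3D pose sequence
#'
#' Convenience wrapper: distance signal, smoothing, candidate extraction,
#' honest-extrema clustering, step segmentation and parameter summary.
#'
#' @param seq `pose_sequence` with `frames3d`.
#' @param cutoff Low-pass cutoff in Hz.
#' @param window_s Honest-extrema clustering window (s); default adaptive.
#' @return A `gait_parameters` object; the step events are in `$per_step`.
#' @export
analyze_gait <- function(seq, cutoff = 6, window_s = NULL) {
  sig_raw <- foot_distance_signal(seq)
  sig <- smooth_signal(sig_raw, cutoff)
  hon <- honest_extrema(extrema_candidates(sig), sig, window_s)
  dir <- walking_direction(seq)
  ev <- segment_steps(hon, seq, sig_raw, dir)
  rec <- step_metrics(ev, seq, dir)
  summarize_gait(rec, seq, ev, dir)
}

#' Foot height above the ground plane
#'
#' Vertical ankle coordinate above an estimated ground plane (the 5th
#' percentile of that ankle's heights over the trial — a noise-robust zero
#' during stance), with per-swing maxima extracted from the smoothed series.
#'
#' @param seq `pose_sequence` with `frames3d`.
#' @param side `"L"` or `"R"`.
#' @param cutoff Low-pass cutoff (Hz).
#' @return List with `t`, `height` (m above ground), and `swing_maxima`
#'   (data.frame `frame`, `t`, `height`).
#' @export
foot_height_series <- function(seq, side = c("L", "R"), cutoff = 6) {
  side <- match.arg(side)
  j <- paste0(side, "Ankle")
  y <- seq$frames3d[, j, 2]
  if (any(!is.finite(y))) stop("missing ", j, " in some frames")
  if (!is.na(cutoff) && cutoff < seq$fps / 2)
    y <- lowpass_series(y, cutoff, seq$fps)
  ground <- stats::quantile(y, 0.05, names = FALSE)
  h <- y - ground
  n <- length(h)
  sw <- data.frame(frame = integer(), t = numeric(), height = numeric())
  if (n >= 3L) {
    ismax <- which(h[2:(n - 1)] > h[1:(n - 2)] & h[2:(n - 1)] >= h[3:n]) + 1L
    ismax <- ismax[h[ismax] > 0.4 * max(h)]   # true swings, not stance ripple
    if (length(ismax) > 0L)
      sw <- data.frame(frame = ismax - 1L, t = (ismax - 1L) / seq$fps,
                       height = h[ismax])
  }
  list(t = frame_times(seq), height = h, swing_maxima = sw)
}

#' Kinematic joint-angle series
#'
#' `"knee"`: angle at the knee between the thigh (hip - knee) and shank
#' (ankle - knee) vectors, 180 degrees for a straight leg. `"hip_frontal"` /
#' `"hip_sagittal"`: inclination of the thigh vector from vertical, projected
#' onto the frontal (lateral-vertical) or sagittal (walking-direction-
#' vertical) plane defined by the walking direction.
#'
#' @param seq `pose_sequence` with `frames3d`.
#' @param angle One of `"knee"`, `"hip_frontal"`, `"hip_sagittal"`.
#' @param side `"L"` or `"R"`.
#' @param direction Walking direction (for the hip planes); default
#'   [walking_direction()].
#' @return List of class `angle_series`: `name`, `t` (s), `theta` (degrees).
#' @export
joint_angle_series <- function(seq, angle = c("knee", "hip_frontal",
                                              "hip_sagittal"),
                               side = c("L", "R"), direction = NULL) {
  angle <- match.arg(angle); side <- match.arg(side)
  a3 <- seq$frames3d
  hip <- a3[, paste0(side, "Hip"), , drop = TRUE]
  knee <- a3[, paste0(side, "Knee"), , drop = TRUE]
  ankle <- a3[, paste0(side, "Ankle"), , drop = TRUE]
  if (is.null(dim(hip))) {
    hip <- matrix(hip, 1); knee <- matrix(knee, 1); ankle <- matrix(ankle, 1)
  }
  if (angle == "knee") {
    u <- hip - knee; v <- ankle - knee
    nu <- row_norms(u); nv <- row_norms(v)
    if (any(nu < 1e-9) || any(nv < 1e-9))
      stop("zero-length defining vector for the knee angle")
    cosang <- clamp(rowSums(u * v) / (nu * nv), -1, 1)
    theta <- acos(cosang) * 180 / pi
  } else {
    if (is.null(direction)) direction <- walking_direction(seq)
    lat <- unit(cross3(c(0, 1, 0), direction))
    thv <- knee - hip                       # thigh vector, points down-ish
    axis1 <- if (angle == "hip_frontal") lat else direction
    comp1 <- thv[, 1] * axis1[1] + thv[, 2] * axis1[2] + thv[, 3] * axis1[3]
    compv <- -thv[, 2]                      # downward component
    if (any(abs(comp1) < 1e-12 & abs(compv) < 1e-12))
      stop("zero-length defining vector for the hip angle")
    theta <- atan2(comp1, compv) * 180 / pi
  }
  structure(list(name = paste(angle, side), t = frame_times(seq),
                 theta = theta), class = "angle_series")
}
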