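#' Inter-foot distance signal
#'
#' The step-detection carrier: the walking foot's distance to a reference
#' joint changes periodically, peaking each time the moving foot has covered
#' the step length and dipping as it passes the reference. The default mode
#' measures the Euclidean distance between the two ankles each frame; the
#' alternative measures one ankle against any named reference joint (with the
#' other ankle as reference the two modes coincide).
#'
#' @param seq `pose_sequence` with `frames3d` containing both ankles.
#' @param mode `"ankle-to-ankle"` or `"foot-to-reference-joint"`.
#' @param foot,reference Joint names used in reference mode.
#' @return A list of class `distance_signal`: `t` (s), `d` (m), `fps`, `mode`.
#' @export
foot_distance_signal <- function(seq, mode = c("ankle-to-ankle",
                                               "foot-to-reference-joint"),
                                 foot = "LAnkle", reference = "RAnkle") {
  mode <- match.arg(mode)
  stopifnot(!is.null(seq$frames3d))
  if (mode == "ankle-to-ankle") { foot <- "LAnkle"; reference <- "RAnkle" }
  A <- seq$frames3d[, foot, , drop = TRUE]
  B <- seq$frames3d[, reference, , drop = TRUE]
  if (is.null(dim(A))) { A <- matrix(A, 1); B <- matrix(B, 1) }
  miss <- !apply(is.finite(A) & is.finite(B), 1, all)
  if (any(miss))
    stop("missing ", foot, "/", reference, " at frame ", which(miss)[1] - 1L)
  structure(list(t = frame_times(seq), d = row_norms(A - B),
                 fps = seq$fps, mode = mode), class = "distance_signal")
}

#' Zero-phase low-pass filtering of a distance signal
#'
#' Forward-backward 4th-order Butterworth low-pass (zero phase shift, so
#' extremum timing is preserved), with even reflection padding to suppress
#' edge transients. Constant signals pass through unchanged; output length
#' equals input length. Default cutoff 6 Hz: the gait fundamental stays below
#' about 2 Hz even for fast walkers, while estimator jitter is broadband.
#'
#' @param sig A `distance_signal` (or any list with `d` and `fps`).
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @return The signal with `d` replaced by its filtered version.
#' @export
smooth_signal <- function(sig, cutoff = 6) {
  if (cutoff >= sig$fps / 2)
    stop("cutoff must be below the Nyquist frequency (", sig$fps / 2, " Hz)")
  sig$d <- lowpass_series(sig$d, cutoff, sig$fps)
  sig
}

# zero-phase Butterworth low-pass of one numeric series, reflect-padded
lowpass_series <- function(x, cutoff, fps) {
  n <- length(x)
  if (n < 7L) return(x)
  bf <- signal::butter(4, cutoff / (fps / 2), type = "low")
  np <- min(n - 1L, as.integer(ceiling(fps)))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- signal::filtfilt(bf, xp)
  y[(np + 1):(np + n)]
}

# zero-phase low-pass every coordinate track of a frames3d array
smooth_tracks <- function(a3, cutoff, fps) {
  for (j in seq_len(dim(a3)[2])) for (k in seq_len(dim(a3)[3])) {
    x <- a3[, j, k]
    if (all(is.finite(x))) a3[, j, k] <- lowpass_series(x, cutoff, fps)
  }
  a3
}

#' Raw extremum candidates of a distance signal
#'
#' Exhaustive neighbor-comparison scan (no thresholding): every interior
#' sample that is `>=` both neighbors is a maximum candidate, `<=` both a
#' minimum candidate. Runs of equal values (plateaus) emit one candidate at
#' each run endpoint instead of one per sample.
#'
#' @param sig A `distance_signal` with at least 3 samples.
#' @return data.frame with columns `frame` (0-based), `kind`
#'   (`"max"`/`"min"`), `value`.
#' @export
extrema_candidates <- function(sig) {
  d <- sig$d
  n <- length(d)
  if (n < 3L) stop("need at least 3 samples")
  r <- rle(d)
  m <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  if (m >= 3L) {
    for (i in 2:(m - 1L)) {
      vi <- r$values[i]
      kind <- if (vi > r$values[i - 1L] && vi > r$values[i + 1L]) "max"
      else if (vi < r$values[i - 1L] && vi < r$values[i + 1L]) "min"
      else next
      fr <- unique(c(starts[i], ends[i]))
      out[[length(out) + 1L]] <- data.frame(frame = fr - 1L, kind = kind,
                                            value = vi, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(), kind = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$frame), , drop = FALSE]
}

#' Estimate the dominant step period of a distance signal
#'
#' Autocorrelation peak of the mean-removed (smoothed) signal, searched over
#' physiologic step periods (0.25-1.5 s). Falls back to the median spacing of
#' maximum candidates when no autocorrelation peak exists.
#'
#' @param sig A `distance_signal` (smooth it first for noisy data).
#' @return Step period in seconds.
#' @export
estimate_step_period <- function(sig) {
  d <- sig$d - mean(sig$d)
  fps <- sig$fps
  lo <- max(2L, as.integer(round(0.25 * fps)))
  hi <- min(length(d) - 2L, as.integer(round(1.5 * fps)))
  if (hi > lo + 1L) {
    ac <- stats::acf(d, lag.max = hi, plot = FALSE, demean = FALSE)$acf[, 1, 1]
    lag <- lo:hi
    v <- ac[lag + 1L]
    ismax <- which(v >= c(v[1], v[-length(v)]) & v >= c(v[-1], v[length(v)]) &
                     v > 0)
    if (length(ismax) > 0L) return(lag[ismax[which.max(v[ismax])]] / fps)
  }
  cand <- extrema_candidates(sig)
  mx <- cand$frame[cand$kind == "max"]
  if (length(mx) >= 2L) return(stats::median(diff(mx)) / fps)
  stop("cannot estimate step period: too few extrema")
}

#' Cluster extremum candidates into honest extrema
#'
#' In real data a double-support phase produces several spurious local
#' extrema per true gait event. Plateau-run duplicates collapse to their most
#' extreme member (ties resolved to the earliest frame); the resulting
#' strictly alternating sequence is then simplified by persistence: adjacent
#' max/min pairs whose value difference is a small fraction of the signal's
#' full swing — double-support ripple or noise wiggles, never a true step,
#' which always swings between the step-length peak and the feet-passing
#' trough — are cancelled pairwise, smallest first, which preserves
#' alternation and keeps the best member of each genuine peak. The survivors
#' are trimmed to start and end on an honest maximum; candidates of the same
#' kind within a temporal window (default a quarter of the estimated step
#' period) of a representative form its cluster.
#'
#' @param candidates Output of [extrema_candidates()].
#' @param sig The `distance_signal` the candidates came from.
#' @param window_s Clustering window in seconds; default
#'   `0.25 * estimate_step_period(sig)`.
#' @param min_prominence Adjacent max-min pairs whose amplitude is below this
#'   fraction of the signal's full swing are cancelled as noise.
#' @return data.frame of class `honest_extrema` with columns `frame`, `kind`,
#'   `value`, `members` (list of member frames).
#' @export
honest_extrema <- function(candidates, sig, window_s = NULL,
                           min_prominence = 0.3) {
  if (nrow(candidates) == 0L) stop("insufficient steps: no extremum candidates")
  if (is.null(window_s)) window_s <- 0.25 * estimate_step_period(sig)
  win <- window_s * sig$fps
  cand <- candidates[order(candidates$frame), , drop = FALSE]
  # collapse consecutive same-kind candidates (plateau-run duplicates): keep
  # the most extreme value, ties resolved to the earliest frame
  gid <- cumsum(c(1, cand$kind[-1] != cand$kind[-nrow(cand)]))
  ext <- do.call(rbind, lapply(split(cand, gid), function(g) {
    best <- if (g$kind[1] == "max") which(g$value == max(g$value))
    else which(g$value == min(g$value))
    data.frame(frame = g$frame[best[1L]], kind = g$kind[1],
               value = g$value[best[1L]], stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  # trim leading/trailing non-maximum extrema before simplification: a
  # sequence cut mid-swing ends on a shallow partial trough that is an edge
  # artifact, not a feet-passing event, and must not cancel a true landing
  while (nrow(ext) > 0L && ext$kind[1] != "max") ext <- ext[-1, , drop = FALSE]
  while (nrow(ext) > 0L && ext$kind[nrow(ext)] != "max")
    ext <- ext[-nrow(ext), , drop = FALSE]
  # the sequence now alternates strictly; cancel adjacent max/min pairs of
  # small amplitude (persistence simplification): a double-support ripple or
  # noise wiggle forms a pair whose value difference is a small fraction of
  # the signal's full swing, while every true step swings between the
  # step-length peak and the feet-passing trough
  if (any(ext$kind == "max") && any(ext$kind == "min")) {
    amp <- max(ext$value[ext$kind == "max"]) - min(ext$value[ext$kind == "min"])
    repeat {
      if (nrow(ext) < 3L) break
      dv <- abs(diff(ext$value))
      i <- which.min(dv)
      if (dv[i] >= min_prominence * amp) break
      ext <- ext[-c(i, i + 1L), , drop = FALSE]
    }
  }
  # trim to start and end on a maximum (partial boundary steps are excluded)
  while (nrow(ext) > 0L && ext$kind[1] != "max") ext <- ext[-1, , drop = FALSE]
  while (nrow(ext) > 0L && ext$kind[nrow(ext)] != "max")
    ext <- ext[-nrow(ext), , drop = FALSE]
  if (sum(ext$kind == "max") < 2L)
    stop("insufficient steps: fewer than 2 honest maxima")
  # cluster membership: every candidate of the same kind within the window
  # of a surviving representative belongs to its cluster; candidates closer
  # to a cancelled extremum than to any representative are discarded. The
  # reported frame is the cluster's earliest member: a gait event is the
  # onset of its extremal episode (a double-support dwell forms a plateau
  # whose value-extreme member lands anywhere on it under noise, while the
  # first member tracks the landing itself). This also subsumes the
  # equal-value tie rule. The value stays the cluster's extreme value.
  ext$members <- lapply(seq_len(nrow(ext)), function(i) {
    f <- cand$frame[cand$kind == ext$kind[i] &
                      abs(cand$frame - ext$frame[i]) <= win]
    sort(unique(c(f, ext$frame[i])))
  })
  for (i in seq_len(nrow(ext))) {
    mem <- ext$members[[i]]
    ext$frame[i] <- mem[1L]
    vals <- cand$value[cand$frame %in% mem & cand$kind == ext$kind[i]]
    ext$value[i] <- if (ext$kind[i] == "max") max(vals) else min(vals)
  }
  rownames(ext) <- NULL
  class(ext) <- c("honest_extrema", "data.frame")
  ext
}

#' Segment steps at the honest maxima
#'
#' Each honest maximum of the inter-ankle distance is a foot landing: the
#' moving foot has just covered the step length. The landing side is the
#' ankle that is forward along the walking direction at the landing frame.
#' Landing times are refined to sub-frame precision by quadratic
#' interpolation of the smoothed distance signal around the peak; step
#' intervals are differences of the refined times.
#'
#' @param honest Output of [honest_extrema()].
#' @param seq The `pose_sequence` (with `frames3d`) the signal came from.
#' @param sig Optional raw (unsmoothed) `distance_signal` used for peak
#'   refinement; defaults to the ankle-to-ankle signal of `seq`.
#' @param direction Optional walking direction; default [walking_direction()].
#' @return data.frame of class `step_events` with columns `index`,
#'   `landing_frame` (0-based), `landing_time` (s, refined), `side`,
#'   `interval_to_next` (s, `NA` for the last step).
#' @export
segment_steps <- function(honest, seq, sig = NULL, direction = NULL) {
  mx <- honest[honest$kind == "max", , drop = FALSE]
  if (nrow(mx) < 2L) stop("insufficient steps")
  if (is.null(direction)) direction <- walking_direction(seq)
  if (is.null(sig)) sig <- foot_distance_signal(seq)
  # keep the refinement window inside the cubic-flat region of the peak
  period_frames <- stats::median(diff(mx$frame))
  hw <- as.integer(clamp(round(0.3 * period_frames), 3, 8))
  times <- vapply(mx$frame,
                  function(f) refine_landing(sig$d, f, period_frames,
                                             halfwin = hw),
                  numeric(1)) / sig$fps
  la <- seq$frames3d[mx$frame + 1L, "LAnkle", , drop = FALSE]
  ra <- seq$frames3d[mx$frame + 1L, "RAnkle", , drop = FALSE]
  proj <- function(a) a[, 1, 1] * direction[1] + a[, 1, 2] * direction[2] +
    a[, 1, 3] * direction[3]
  gap <- proj(la) - proj(ra)
  if (any(abs(gap) < 1e-9))
    stop("ambiguous side: ankles coincident along the walking direction")
  side <- ifelse(gap > 0, "L", "R")
  out <- data.frame(index = seq_len(nrow(mx)), landing_frame = mx$frame,
                    landing_time = times, side = side,
                    interval_to_next = c(diff(times), NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("step_events", "data.frame")
  out
}

# Flank shape of a smooth swing: a foot leaving or entering ground contact
# follows an ease curve with vanishing end velocity and acceleration; the
# distance-peak deficit at |t - t_k| = u is proportional to
# C(u / T_swing) = u/T - sin(2 pi u/T) / (2 pi) (cubic-flat near the peak,
# saturating over one swing period).
peak_flank <- function(u, period) cycloid(clamp(u / period, 0, 1))

# Sub-frame landing-time refinement: fit the two-sided smooth-swing peak
# model d(t) ~ c - A * C((t_k - t)_+ / T) - B * C((t - t_k)_+ / T) to the
# raw samples around the detected frame (the flank coefficients differ
# because the adjacent swings differ), profiling the peak location over a
# fine grid with linear least squares at each trial location. Returns the
# refined location in frames (0-based).
refine_landing <- function(d, f0, period_frames, halfwin = 4L,
                           span = 1.25, by = 0.05) {
  n <- length(d)
  i0 <- f0 + 1L
  j <- max(1L, i0 - halfwin):min(n, i0 + halfwin)
  if (length(j) < 5L) return(as.numeric(f0))
  tj <- j - 1
  y <- d[j]
  grid <- seq(f0 - span, f0 + span, by = by)
  sse <- vapply(grid, function(tk) {
    X <- cbind(1, -peak_flank(tk - tj, period_frames),
               -peak_flank(tj - tk, period_frames))
    fit <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    sum((y - X %*% fit)^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# Fitted plateau value of the smooth-swing peak model at a known (refined)
# peak location tk; y are samples at frame positions tj. Reads the peak
# value of a flat-topped extremum without argmax or averaging bias.
peak_plateau_value <- function(y, tj, tk, period_frames) {
  X <- cbind(1, -peak_flank(tk - tj, period_frames),
             -peak_flank(tj - tk, period_frames))
  fit <- tryCatch(qr.solve(X, y), error = function(e) NULL)
  if (is.null(fit)) return(max(y))
  fit[1]
}
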