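#' Skeleton optimizer configuration
#'
#' Weights and controls for the four-term energy minimized by
#' [optimize_sequence()]:
#' * an inverse-kinematics term comparing candidate joints with 3D points
#'   back-lifted from the 2D keypoints along the pixel ray at the candidate's
#'   own depth (m^2);
#' * a reprojection term comparing the candidate's pinhole projection with
#'   the 2D keypoints (normalized by focal length, i.e. squared angular
#'   error);
#' * a temporal-smoothness hinge on per-joint frame-to-frame displacement
#'   beyond a velocity allowance;
#' * a depth-damping hinge on frame-to-frame change of the root (pelvis)
#'   depth beyond a depth-rate allowance.
#'
#' The allowances are set above the joint speeds of ordinary walking so that
#' a clean walk is a zero-energy fixed point and only estimation jitter is
#' penalized.
#'
#' @param weights Numeric length 4, `(lambda_ik, lambda_proj, lambda_smooth,
#'   lambda_depth)`, all >= 0, at least one positive.
#' @param max_iterations Maximum descent iterations (>= 1).
#' @param convergence_tol Relative total-energy change below which descent
#'   stops.
#' @param smooth_allow Joint-speed allowance, m/s.
#' @param depth_allow Root depth-rate allowance, m/s.
#' @param prefilter_cutoff Cutoff (Hz) of the zero-phase low-pass applied to
#'   the raw 3D tracks before descent (estimator noise is white, walking
#'   motion is not). An input whose energy already vanishes is perfectly
#'   self-consistent and passes through unfiltered, preserving the exact
#'   noiseless fixed point. `NA` disables the filter.
#' @param focal,principal_point Camera intrinsics (device metadata).
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(weights = c(1, 1, 0.5, 0.5),
                             max_iterations = 200L, convergence_tol = 1e-6,
                             smooth_allow = 8, depth_allow = 4,
                             prefilter_cutoff = 7,
                             focal = 1400, principal_point = c(540, 960)) {
  stopifnot(length(weights) == 4L, all(weights >= 0), any(weights > 0),
            max_iterations >= 1L, convergence_tol > 0,
            smooth_allow >= 0, depth_allow >= 0, focal > 0,
            length(principal_point) == 2L)
  structure(list(weights = as.numeric(weights),
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 smooth_allow = smooth_allow, depth_allow = depth_allow,
                 prefilter_cutoff = prefilter_cutoff,
                 focal = focal, principal_point = as.numeric(principal_point)),
            class = "optimizer_config")
}

# Core energy + gradient over a candidate frames3d array.
# a3: n x j x 3 candidate (finite); u, v: n x j raw 2D (NA allowed);
# zraw: n x j depth (z) of the raw monocular 3D estimates, used to back-lift
# the 2D keypoints into fixed metric anchor points for the IK term.
# Returns list(breakdown, grad array) — grad only when grad = TRUE.
energy_core <- function(a3, u, v, zraw, camera, config, grad = FALSE, fps) {
  lam <- config$weights
  n <- dim(a3)[1]; nj <- dim(a3)[2]
  cx <- camera$position[1]; cy <- camera$position[2]; cz <- camera$position[3]
  fl <- camera$focal; u0 <- camera$principal_point[1]
  v0 <- camera$principal_point[2]
  X <- a3[, , 1] - cx; Y <- a3[, , 2] - cy; Z <- a3[, , 3] - cz
  w <- is.finite(u) & is.finite(v) & is.finite(zraw)
  N1 <- max(sum(w), 1L)
  a <- (u - u0) / fl; b <- (v0 - v) / fl
  a[!w] <- 0; b[!w] <- 0
  # inverse-kinematics term (meters^2): distance, transverse to the pixel
  # ray, between the candidate and the 2D keypoint back-lifted at the raw
  # monocular depth — a fixed data-fusion anchor of the two detector stages
  Zr <- zraw - cz
  Zr[!w] <- 1
  rx <- (X - a * Zr) * w; ry <- (Y - b * Zr) * w; rz <- (Z - Zr) * w
  e_ik_f <- rowSums(rx^2 + ry^2 + rz^2)
  e_ik <- lam[1] * sum(e_ik_f) / N1
  # reprojection term (angular^2 = px^2 / focal^2)
  s <- (X / Z - a) * w; q <- (Y / Z - b) * w
  e_pr_f <- rowSums(s^2 + q^2)
  e_proj <- lam[2] * sum(e_pr_f) / N1
  # smoothness hinge
  allow_s <- config$smooth_allow / fps
  if (n > 1) {
    DX <- X[-1, , drop = FALSE] - X[-n, , drop = FALSE]
    DY <- Y[-1, , drop = FALSE] - Y[-n, , drop = FALSE]
    DZ <- Z[-1, , drop = FALSE] - Z[-n, , drop = FALSE]
    dnorm_ <- sqrt(DX^2 + DY^2 + DZ^2)
    ex <- pmax(dnorm_ - allow_s, 0)
    N2 <- (n - 1) * nj
    e_sm_f <- c(0, rowSums(ex^2))
    e_smooth <- lam[3] * sum(e_sm_f) / N2
  } else {
    e_sm_f <- 0; e_smooth <- 0; N2 <- 1L
  }
  # depth-damping hinge on the pelvis
  root <- "Pelvis"
  if (n > 1) {
    dz <- Z[-1, root] - Z[-n, root]
    allow_d <- config$depth_allow / fps
    exd <- pmax(abs(dz) - allow_d, 0)
    N3 <- n - 1
    e_dp_f <- c(0, exd^2)
    e_depth <- lam[4] * sum(e_dp_f) / N3
  } else {
    e_dp_f <- 0; e_depth <- 0; N3 <- 1L
  }
  br <- structure(list(
    e_ik = e_ik, e_proj = e_proj, e_smooth = e_smooth, e_depth = e_depth,
    e_total = e_ik + e_proj + e_smooth + e_depth,
    per_frame = lam[1] * e_ik_f / N1 + lam[2] * e_pr_f / N1 +
      lam[3] * e_sm_f / N2 + lam[4] * e_dp_f / N3),
    class = "energy_breakdown")
  if (!grad) return(list(breakdown = br, grad = NULL))

  gX <- 2 * lam[1] / N1 * rx + 2 * lam[2] / N1 * s / Z
  gY <- 2 * lam[1] / N1 * ry + 2 * lam[2] / N1 * q / Z
  # depth is deliberately not descended along the projection term — depth
  # from projected scale is ill-conditioned under shape noise; instead the
  # IK anchor's depth residual pins each joint's depth to the back-lift
  # depth, so bone re-normalization cannot trade depth drift for a better
  # image-plane fit
  gZ <- 2 * lam[1] / N1 * rz
  if (n > 1 && lam[3] > 0) {
    dn <- dnorm_; dn[dn < 1e-12] <- 1
    cf <- 2 * lam[3] / N2 * ex / dn
    gX[-1, ] <- gX[-1, ] + cf * DX; gX[-n, ] <- gX[-n, ] - cf * DX
    gY[-1, ] <- gY[-1, ] + cf * DY; gY[-n, ] <- gY[-n, ] - cf * DY
    gZ[-1, ] <- gZ[-1, ] + cf * DZ; gZ[-n, ] <- gZ[-n, ] - cf * DZ
  }
  if (n > 1 && lam[4] > 0) {
    cfd <- 2 * lam[4] / N3 * exd * sign(dz)
    gZ[-1, root] <- gZ[-1, root] + cfd
    gZ[-n, root] <- gZ[-n, root] - cfd
  }
  G <- array(0, dim(a3))
  G[, , 1] <- gX; G[, , 2] <- gY; G[, , 3] <- gZ
  list(breakdown = br, grad = G)
}

#' Energy breakdown of a candidate skeleton sequence
#'
#' Evaluates the four energy terms for a candidate 3D sequence against the
#' raw 2D keypoints, without optimizing. The IK term back-lifts each 2D
#' keypoint along its pixel ray to the candidate's own depth and measures
#' the candidate's transverse distance to that lifted point; the projection
#' term measures angular reprojection error; the smoothness and depth terms
#' are hinges on frame-to-frame motion beyond their allowances. (During
#' descent, [optimize_sequence()] freezes the back-lift depth at its
#' initialization so the IK anchors are fixed data points.)
#'
#' @param candidate,raw2d,raw3d `pose_sequence`s aligned frame-for-frame
#'   (`candidate` and `raw3d` carry `frames3d`, `raw2d` carries `frames2d`);
#'   `raw3d` seeds the optimizer and is only alignment-checked here.
#' @param camera A [camera_model()].
#' @param config An [optimizer_config()].
#' @return An `energy_breakdown`: `e_ik`, `e_proj`, `e_smooth`, `e_depth`,
#'   `e_total` (their sum) and `per_frame` totals.
#' @export
energy_components <- function(candidate, raw2d, raw3d = NULL, camera, config) {
  stopifnot(inherits(candidate, "pose_sequence"), !is.null(candidate$frames3d),
            !is.null(raw2d$frames2d))
  if (n_frames(candidate) != n_frames(raw2d))
    stop("candidate and raw2d must have the same number of frames")
  if (!is.null(raw3d) && n_frames(raw3d) != n_frames(candidate))
    stop("candidate and raw3d must have the same number of frames")
  energy_core(candidate$frames3d, raw2d$frames2d[, , 1], raw2d$frames2d[, , 2],
              candidate$frames3d[, , 3],
              camera, config, grad = FALSE, fps = candidate$fps)$breakdown
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy: total %.6g (ik %.3g, proj %.3g, smooth %.3g, depth %.3g)\n",
              x$e_total, x$e_ik, x$e_proj, x$e_smooth, x$e_depth))
  invisible(x)
}

# Re-impose target bone lengths by a forward-kinematics pass from the pelvis:
# each child joint is re-placed along its (pre-pass) direction from its
# parent at the target length. Bone directions come from the input array.
renormalize_bones <- function(a3, targets, topology = default_topology()) {
  out <- a3
  for (i in seq_len(nrow(topology$bones))) {
    p <- topology$bones$parent[i]; ch <- topology$bones$child[i]
    D <- a3[, ch, , drop = TRUE] - a3[, p, , drop = TRUE]
    if (is.null(dim(D))) D <- matrix(D, 1)
    nm <- sqrt(rowSums(D^2))
    if (any(!is.finite(nm)) || any(nm < 1e-9))
      stop("unresolvable bone-length constraint: degenerate bone ",
           topology$bones$bone[i], " (coincident joints)")
    L <- targets[[topology$bones$bone[i]]]
    out[, ch, ] <- out[, p, , drop = TRUE] + D / nm * L
  }
  out
}

# Per-frame lateral/vertical translation aligning a bone-true skeleton to
# the 2D keypoints (closed-form least squares on the angular reprojection
# residuals at the frame's own depth). The global-positioning step: the 2D
# keypoints localize the subject precisely in the image plane, so the x/y
# placement is refit; depth is deliberately left at the monocular estimate —
# depth-from-projected-scale is far noisier than the raw estimate once the
# skeleton shape itself carries noise.
align_frames_to_2d <- function(a3, u, v, camera) {
  n <- dim(a3)[1]
  u0 <- camera$principal_point[1]; v0 <- camera$principal_point[2]
  fl <- camera$focal
  for (f in seq_len(n)) {
    w <- which(is.finite(u[f, ]) & is.finite(v[f, ]))
    if (length(w) < 3L) next
    a <- (u[f, w] - u0) / fl
    b <- (v0 - v[f, w]) / fl
    Zc <- a3[f, w, 3] - camera$position[3]
    if (any(Zc < 0.5)) next
    iz <- 1 / Zc
    s <- (a3[f, w, 1] - camera$position[1]) * iz - a
    q <- (a3[f, w, 2] - camera$position[2]) * iz - b
    den <- sum(iz^2)
    tx <- -sum(s * iz) / den
    ty <- -sum(q * iz) / den
    if (is.finite(tx) && is.finite(ty)) {
      a3[f, , 1] <- a3[f, , 1] + tx
      a3[f, , 2] <- a3[f, , 2] + ty
    }
  }
  a3
}

# Linear interpolation over frames for sporadically missing joints.
fill_missing_frames <- function(a3) {
  n <- dim(a3)[1]
  for (j in seq_len(dim(a3)[2])) {
    sl <- a3[, j, , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, 1)
    ok <- apply(is.finite(sl), 1, all)
    if (all(ok)) next
    if (!any(ok))
      stop("joint ", dimnames(a3)[[2]][j], " missing in every 3D frame")
    for (k in 1:3)
      a3[, j, k] <- stats::approx(which(ok), sl[ok, k], xout = seq_len(n),
                                  rule = 2)$y
  }
  a3
}

#' Fit an anatomically consistent 3D skeleton sequence
#'
#' The core monocular fitting stage: starting from the raw 3D estimates
#' re-normalized to the bone lengths implied by the person's height, performs
#' projected gradient descent on the four-term energy of
#' [energy_components()], re-imposing the bone-length constraints after every
#' step (constraint as projection, not penalty). Descent uses backtracking on
#' the projected step, so the recorded energy trace is non-increasing by
#' construction. The camera's extrinsic position is estimated once from the
#' initial candidate via [estimate_camera()] and held stationary.
#'
#' @param raw2d `pose_sequence` with `frames2d` (pixel keypoints).
#' @param raw3d `pose_sequence` with `frames3d` (metric estimates), >= 2
#'   frames; joints missing in some frames are interpolated, joints missing
#'   everywhere are an error.
#' @param height Person height in meters.
#' @param config An [optimizer_config()].
#' @return An object of class `optimized_result`: `seq` (optimized
#'   `pose_sequence` carrying both channels), `camera_distance` (per-frame
#'   root depth, m), `camera` (fitted [camera_model()]), `energy_trace` (list
#'   of `energy_breakdown`, one per accepted iteration, non-increasing
#'   totals), `iterations`, `converged`.
#' @export
optimize_sequence <- function(raw2d, raw3d, height, config = optimizer_config()) {
  stopifnot(inherits(raw2d, "pose_sequence"), inherits(raw3d, "pose_sequence"),
            !is.null(raw2d$frames2d), !is.null(raw3d$frames3d))
  n <- n_frames(raw3d)
  if (n < 2L) stop("optimization needs at least 2 frames")
  if (n_frames(raw2d) != n) stop("raw2d and raw3d must be frame-aligned")
  req <- c("Pelvis", "Neck", "LHip", "RHip", "LKnee", "RKnee", "LAnkle", "RAnkle")
  pres <- apply(is.finite(raw3d$frames3d[, req, , drop = FALSE]), c(1, 2), all)
  if (!all(pres))
    stop("required joints (pelvis, neck, hips, knees, ankles) must be present ",
         "in every 3D frame")
  targets <- target_bone_lengths(height, raw3d$topology)
  C <- fill_missing_frames(raw3d$frames3d)
  C <- renormalize_bones(C, targets, raw3d$topology)

  est <- estimate_camera(raw2d,
                         pose_sequence(frames3d = C, fps = raw3d$fps,
                                       subject = raw3d$subject,
                                       topology = raw3d$topology),
                         config$focal, config$principal_point)
  camera <- est$camera

  u <- raw2d$frames2d[, , 1]; v <- raw2d$frames2d[, , 2]
  fps <- raw3d$fps
  C <- align_frames_to_2d(C, u, v, camera)
  # temporal-consistency stage: estimator noise is white while walking
  # motion is smooth, so the descent is seeded from zero-phase low-passed
  # tracks. An input whose energy already vanishes is perfectly
  # self-consistent — it is its own optimum and passes through unfiltered.
  pc <- config$prefilter_cutoff
  e_raw <- energy_core(C, u, v, C[, , 3], camera, config, grad = FALSE, fps)
  if (!is.na(pc) && pc < fps / 2 && n >= 8L &&
      e_raw$breakdown$e_total > 1e-10) {
    Cf <- smooth_tracks(fill_missing_frames(raw3d$frames3d), pc, fps)
    Cf <- tryCatch(
      align_frames_to_2d(renormalize_bones(Cf, targets, raw3d$topology),
                         u, v, camera),
      error = function(e) NULL)
    if (!is.null(Cf)) C <- Cf
  }
  # the IK back-lift depth is frozen at the initialization's depth: the
  # anchors stay fixed data points and the term remains quadratic in the
  # candidate during descent
  zanc <- C[, , 3]
  ec <- energy_core(C, u, v, zanc, camera, config, grad = TRUE, fps)
  trace <- list(ec$breakdown)
  eta <- 0.02
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    e_old <- ec$breakdown$e_total
    if (e_old <= 1e-14) { converged <- TRUE; break }
    accepted <- FALSE
    while (eta > 1e-9) {
      Ctry <- tryCatch(
        renormalize_bones(C - eta * ec$grad, targets, raw3d$topology),
        error = function(e) NULL)
      if (!is.null(Ctry)) {
        ec_try <- energy_core(Ctry, u, v, zanc, camera, config, grad = TRUE,
                              fps)
        if (ec_try$breakdown$e_total <= e_old) {
          C <- Ctry; ec <- ec_try
          trace[[length(trace) + 1L]] <- ec$breakdown
          eta <- eta * 1.3
          accepted <- TRUE
          break
        }
      }
      eta <- eta / 2
    }
    if (!accepted) { converged <- TRUE; break }
    if (abs(e_old - ec$breakdown$e_total) <= config$convergence_tol *
        max(e_old, 1e-12)) { converged <- TRUE; break }
  }

  dist <- C[, "Pelvis", 3] - camera$position[3]
  out_seq <- pose_sequence(frames3d = C, frames2d = raw2d$frames2d,
                           fps = fps, subject = raw3d$subject,
                           topology = raw3d$topology)
  structure(list(seq = out_seq, camera_distance = as.numeric(dist),
                 camera = camera, energy_trace = trace,
                 iterations = iter, converged = converged),
            class = "optimized_result")
}

#' @export
print.optimized_result <- function(x, ...) {
  e0 <- x$energy_trace[[1]]$e_total
  e1 <- x$energy_trace[[length(x$energy_trace)]]$e_total
  cat(sprintf("<optimized_result> %d frames, %d iterations (%s), energy %.4g -> %.4g\n",
              n_frames(x$seq), x$iterations,
              if (x$converged) "converged" else "max iterations", e0, e1))
  cat(sprintf("  camera distance %.2f -> %.2f m\n",
              x$camera_distance[1], x$camera_distance[length(x$camera_distance)]))
  invisible(x)
}

#' Estimate the stationary camera position
#'
#' Least-squares placement of an axis-aligned pinhole camera (known focal
#' length and principal point, unknown position) minimizing the reprojection
#' error of the candidate 3D sequence against the 2D keypoints over all
#' frames. The depth coordinate is profiled: for a trial camera depth the
#' optimal lateral/vertical offsets are closed-form, leaving a smooth 1-D
#' problem solved by golden-section search and polished locally.
#'
#' @param raw2d `pose_sequence` with `frames2d`.
#' @param candidate3d `pose_sequence` with `frames3d`, frame-aligned.
#' @param focal Focal length, pixels.
#' @param principal_point `(u0, v0)` pixels.
#' @return List with `camera` (fitted [camera_model()]), `distance`
#'   (per-frame pelvis depth in meters), `rmse_px` (reprojection RMSE), and
#'   `position_rel_frame0` (camera position in the skeleton-centered frame of
#'   frame 0).
#' @export
estimate_camera <- function(raw2d, candidate3d, focal,
                            principal_point = c(540, 960)) {
  stopifnot(!is.null(raw2d$frames2d), !is.null(candidate3d$frames3d))
  if (n_frames(raw2d) != n_frames(candidate3d))
    stop("sequences must be frame-aligned")
  u <- as.vector(raw2d$frames2d[, , 1]); v <- as.vector(raw2d$frames2d[, , 2])
  X <- as.vector(candidate3d$frames3d[, , 1])
  Y <- as.vector(candidate3d$frames3d[, , 2])
  Z <- as.vector(candidate3d$frames3d[, , 3])
  ok <- is.finite(u) & is.finite(v) & is.finite(X) & is.finite(Y) & is.finite(Z)
  if (sum(ok) < 4L) stop("degenerate geometry: too few joint observations")
  u <- u[ok]; v <- v[ok]; X <- X[ok]; Y <- Y[ok]; Z <- Z[ok]
  P <- cbind(X, Y, Z)
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[2] < 1e-9) stop("degenerate geometry: 3D joints are collinear")
  du <- u - principal_point[1]
  dv <- principal_point[2] - v
  fit_xy <- function(cz) {
    Zc <- Z - cz
    w2 <- 1 / Zc^2
    cx <- (sum(X * w2) - sum(du / (focal * Zc))) / sum(w2)
    cy <- (sum(Y * w2) - sum(dv / (focal * Zc))) / sum(w2)
    ru <- focal * (X - cx) / Zc - du
    rv <- focal * (Y - cy) / Zc - dv
    list(cx = cx, cy = cy, sse = sum(ru^2 + rv^2))
  }
  zmin <- min(Z)
  lo <- zmin - 20; hi <- zmin - 0.15
  opt <- stats::optimize(function(cz) fit_xy(cz)$sse, c(lo, hi), tol = 1e-12)
  cz <- opt$minimum
  xy <- fit_xy(cz)
  cam <- camera_model(focal, principal_point, c(xy$cx, xy$cy, cz))
  pelvis_z <- candidate3d$frames3d[, "Pelvis", 3]
  root0 <- candidate3d$frames3d[1, "Pelvis", ]
  list(camera = cam,
       distance = as.numeric(pelvis_z - cz),
       rmse_px = sqrt(xy$sse / (2 * length(u))),
       position_rel_frame0 = as.numeric(cam$position - root0))
}
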