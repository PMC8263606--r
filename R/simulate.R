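#' Gait scenario for the synthetic walker
#'
#' Parameters of one simulated frontal-view walk: a subject approaches a
#' near-stationary camera over a few meters. Exactly two of
#' `gait_speed`, `cadence`, `step_length` may be given; the third is derived
#' from the identity `gait_speed = step_length * cadence / 60` (if all three
#' are given they must satisfy it to 1e-6 relative).
#'
#' Defaults place the walk at the operating point of elderly walkers on an
#' instrumented walkway (speed about 1.4 m/s, cadence about 120 steps/min,
#' step time 0.5 s) with mild step-to-step variability.
#'
#' @param gait_speed m/s.
#' @param cadence steps/min.
#' @param step_length m.
#' @param step_time_cv,step_length_cv Coefficients of variation of the
#'   per-step durations / lengths (unitless, >= 0).
#' @param n_steps Number of steps (>= 2).
#' @param fps Frames per second (>= 10; default 30, smartphone convention).
#' @param foot_clearance Peak swing-foot lift in meters.
#' @param pelvis_sway Lateral pelvis sway amplitude in meters.
#' @param step_width Lateral distance between left and right foot lines, m.
#' @param dwell Double-support dwell in seconds: after each landing both feet
#'   stay grounded this long before the next swing (0 = instantaneous).
#' @param walk_direction Unit vector in the ground plane (y = 0 component);
#'   default `c(0, 0, -1)`, straight toward the camera.
#' @param noise3d_sigma Per-axis 3D estimation noise SD in meters.
#' @param depth_noise_factor Multiplier (>= 1) applied to the z-axis noise SD,
#'   reflecting the larger monocular depth uncertainty.
#' @param noise2d_sigma 2D keypoint noise SD in pixels.
#' @param height Subject height in meters.
#' @param subject_id Label.
#' @param seed Integer seed; every stochastic operation derives from it.
#' @return A list of class `gait_scenario` with all fields resolved.
#' @examples
#' sc <- gait_scenario(step_length = 0.70, cadence = 120)
#' sc$gait_speed  # 1.4
#' @export
gait_scenario <- function(gait_speed = NULL, cadence = NULL, step_length = NULL,
                          step_time_cv = 0.04, step_length_cv = 0.04,
                          n_steps = 8, fps = 30,
                          foot_clearance = 0.05, pelvis_sway = 0.02,
                          step_width = 0.10, dwell = 0,
                          walk_direction = c(0, 0, -1),
                          noise3d_sigma = 0, depth_noise_factor = 2,
                          noise2d_sigma = 0,
                          height = 1.70, subject_id = "sim", seed = 1L) {
  tri <- resolve_gait_triple(gait_speed, cadence, step_length)
  if (step_time_cv < 0 || step_length_cv < 0 || noise3d_sigma < 0 ||
      noise2d_sigma < 0)
    stop("dispersions and noise levels must be >= 0")
  if (depth_noise_factor < 1) stop("depth_noise_factor must be >= 1")
  if (fps < 10) stop("fps must be >= 10")
  if (n_steps < 2) stop("n_steps must be >= 2 (no step interval measurable)")
  wd <- as.numeric(walk_direction)
  if (length(wd) != 3L || abs(wd[2]) > 1e-9)
    stop("walk_direction must be a length-3 vector in the ground plane (y = 0)")
  wd <- unit(wd)
  if (dwell < 0 || dwell >= 0.8 * 60 / tri$cadence)
    stop("dwell must be >= 0 and well below the step time")
  structure(c(tri, list(
    step_time_cv = step_time_cv, step_length_cv = step_length_cv,
    n_steps = as.integer(n_steps), fps = fps,
    foot_clearance = foot_clearance, pelvis_sway = pelvis_sway,
    step_width = step_width, dwell = dwell, walk_direction = wd,
    noise3d_sigma = noise3d_sigma, depth_noise_factor = depth_noise_factor,
    noise2d_sigma = noise2d_sigma, height = height,
    subject_id = subject_id, seed = as.integer(seed))),
    class = "gait_scenario")
}

#' Complete the speed/cadence/step-length triple
#'
#' Given exactly two of the three linked gait quantities, derives the third
#' from `gait_speed = step_length * cadence / 60`. With all three given they
#' are checked for consistency (1e-6 relative); with fewer than two, an error.
#'
#' @param gait_speed m/s or `NULL`.
#' @param cadence steps/min or `NULL`.
#' @param step_length m or `NULL`.
#' @return List with all three fields.
#' @export
resolve_gait_triple <- function(gait_speed = NULL, cadence = NULL,
                                step_length = NULL) {
  given <- !vapply(list(gait_speed, cadence, step_length), is.null, logical(1))
  if (sum(given) < 2L)
    stop("at least two of gait_speed, cadence, step_length must be given")
  if (sum(given) == 3L) {
    implied <- step_length * cadence / 60
    if (abs(implied - gait_speed) > 1e-6 * max(abs(gait_speed), 1e-12))
      stop("inconsistent triple: gait_speed != step_length * cadence / 60")
  } else if (is.null(gait_speed)) {
    gait_speed <- step_length * cadence / 60
  } else if (is.null(cadence)) {
    cadence <- 60 * gait_speed / step_length
  } else {
    step_length <- 60 * gait_speed / cadence
  }
  if (gait_speed <= 0 || cadence <= 0 || step_length <= 0)
    stop("gait quantities must be positive")
  list(gait_speed = gait_speed, cadence = cadence, step_length = step_length)
}

# How far in front of the camera (m, along the optical axis) the walk ends.
END_CLEARANCE <- 2.2

#' Generate a ground-truthed synthetic walk
#'
#' Builds a noiseless 3D pose sequence of a subject walking along
#' `walk_direction` toward the camera, together with the exact per-step
#' ground truth. The kinematic model: sampled per-step durations and lengths;
#' ground-fixed stance feet; cycloidal swing-foot advance with a half-sine
#' vertical lift to `foot_clearance`; pelvis midway between the feet with a
#' small lateral sway; knees placed by exact two-link inverse kinematics so
#' every bone length equals [target_bone_lengths()] of the subject height in
#' every frame; anti-phase pendulum arms populate the upper body.
#'
#' The walk ends shortly after the last landing with the start of a closing
#' swing, so the last landing is an interior maximum of the inter-ankle
#' distance signal.
#'
#' @param scenario A [gait_scenario()].
#' @param camera Camera used as ground truth for rendering and distance
#'   checks; the subject's path ends about 2.2 m in front of it.
#' @param first_side `"R"` or `"L"`: side of the first step.
#' @return A list with `seq` (noiseless `pose_sequence` with `frames3d`) and
#'   `truth` (class `gait_ground_truth`): `step_events` (data.frame `time`,
#'   `side`, `frame`), `step_lengths` (m), `step_times` (s), `true_averages`,
#'   `camera_truth`, `camera_distance` (per-frame m), `walk_direction`.
#' @export
generate_walk <- function(scenario,
                          camera = camera_model(1400, c(540, 960), c(0, 1.2, 0)),
                          first_side = "R") {
  stopifnot(inherits(scenario, "gait_scenario"))
  sc <- scenario
  tl <- target_bone_lengths(sc$height)
  anth <- anthropometry_table()
  ankle_h <- anth$ankle_height_fraction * sc$height

  Tbar <- 60 / sc$cadence
  Lbar <- sc$step_length
  n <- sc$n_steps
  smp <- with_seed(sc$seed, list(
    Tk = Tbar * clamp(1 + sc$step_time_cv * stats::rnorm(n), 0.5, 1.5),
    Lk = Lbar * clamp(1 + sc$step_length_cv * stats::rnorm(n), 0.5, 1.5)))
  Tk <- smp$Tk; Lk <- smp$Lk
  if (any(Tk <= sc$dwell + 0.1 * Tbar))
    stop("sampled step time too short for the requested dwell")
  tk <- cumsum(Tk)                     # landing times, t0 = 0
  pk <- cumsum(Lk)                     # landing axial positions
  sides <- rep(c(first_side, setdiff(c("L", "R"), first_side)),
               length.out = n)

  fwd <- sc$walk_direction
  up <- c(0, 1, 0)
  lat <- unit(cross3(up, fwd))         # walker's left

  trail <- sc$dwell + 0.35 * (Tbar - sc$dwell)
  dur <- tk[n] + trail
  nf <- floor(dur * sc$fps) + 1L
  tt <- (seq_len(nf) - 1L) / sc$fps

  # axial foot positions and lift heights
  sF <- list(L = rep(0, nf), R = rep(0, nf))
  hF <- list(L = rep(0, nf), R = rep(0, nf))
  t_prev <- c(0, tk)
  p_start <- function(k) if (k <= 2L) 0 else pk[k - 2L]
  for (k in seq_len(n)) {
    s0 <- p_start(k); s1 <- pk[k]
    a <- t_prev[k] + sc$dwell; b <- tk[k]
    idx <- which(tt >= a)
    tau <- clamp((tt[idx] - a) / (b - a), 0, 1)
    side <- sides[k]
    sF[[side]][idx] <- s0 + (s1 - s0) * cycloid(tau)
    hF[[side]][idx] <- ifelse(tau > 0 & tau < 1,
                              sc$foot_clearance * sin(pi * tau), 0)
  }
  # closing swing of the trailing foot after the last landing
  tr_side <- sides[n - 1L]
  a <- tk[n] + sc$dwell; b <- tk[n] + sc$dwell + (Tbar - sc$dwell)
  idx <- which(tt >= a)
  if (length(idx) > 0L) {
    tau <- clamp((tt[idx] - a) / (b - a), 0, 1)
    s0 <- pk[n - 1L]; s1 <- pk[n] + Lbar
    sF[[tr_side]][idx] <- s0 + (s1 - s0) * cycloid(tau)
    hF[[tr_side]][idx] <- ifelse(tau > 0 & tau < 1,
                                 sc$foot_clearance * sin(pi * tau), 0)
  }

  # continuous step phase and per-frame step index
  stepk <- findInterval(tt, c(0, tk), rightmost.closed = FALSE)  # 1..n+1
  kk <- pmin(stepk, n)
  tau_all <- clamp((tt - t_prev[kk]) / Tk[kk], 0, 1)

  pel_ax <- (sF$L + sF$R) / 2
  sway_sign <- ifelse(sides[kk] == "R", 1, -1)   # toward the stance side
  pel_lat <- sc$pelvis_sway * sway_sign * sin(pi * tau_all)

  # world placement: walk ends END_CLEARANCE in front of the camera
  total <- pk[n] + Lbar
  origin <- c(camera$position[1], 0, camera$position[3] + END_CLEARANCE) -
    fwd * total

  place <- function(ax, latc, y)
    cbind(origin[1] + ax * fwd[1] + latc * lat[1],
          y,
          origin[3] + ax * fwd[3] + latc * lat[3])

  footlat <- c(L = sc$step_width / 2, R = -sc$step_width / 2)
  ankL <- place(sF$L, footlat["L"], ankle_h + hF$L)
  ankR <- place(sF$R, footlat["R"], ankle_h + hF$R)

  hipoff <- tl[["Pelvis-LHip"]]
  thigh <- tl[["LHip-LKnee"]]; shank <- tl[["LKnee-LAnkle"]]
  R_leg <- 0.995 * (thigh + shank)
  hip_lat <- list(L = pel_lat + hipoff, R = pel_lat - hipoff)
  v_leg <- function(side) {
    axd <- sF[[side]] - pel_ax
    ltd <- footlat[[side]] - hip_lat[[side]]
    horiz2 <- axd^2 + ltd^2
    if (any(horiz2 >= R_leg^2))
      stop("step length too large for the leg length at this height")
    # hip sits where the extended leg just reaches the grounded ankle
    sqrt(R_leg^2 - horiz2)
  }
  vy <- pmin(v_leg("L"), v_leg("R"))
  hip_y <- ankle_h + vy

  pelvis <- place(pel_ax, pel_lat, hip_y)
  hipL <- place(pel_ax, hip_lat$L, hip_y)
  hipR <- place(pel_ax, hip_lat$R, hip_y)

  knee_ik <- function(H, A) {
    D <- A - H
    d <- row_norms(D)
    e <- D / d
    mu <- (thigh^2 + d^2 - shank^2) / (2 * d)
    q <- sqrt(pmax(thigh^2 - mu^2, 0))
    fdote <- e[, 1] * fwd[1] + e[, 2] * fwd[2] + e[, 3] * fwd[3]
    nvec <- cbind(fwd[1] - fdote * e[, 1],
                  fwd[2] - fdote * e[, 2],
                  fwd[3] - fdote * e[, 3])
    nn <- row_norms(nvec)
    nn[nn < 1e-9] <- 1
    nvec <- nvec / nn
    H + mu * e + q * nvec
  }
  kneeL <- knee_ik(hipL, ankL)
  kneeR <- knee_ik(hipR, ankR)

  upm <- matrix(up, nf, 3, byrow = TRUE)
  chest <- pelvis + tl[["Pelvis-Chest"]] * upm
  neck <- chest + tl[["Chest-Neck"]] * upm
  head <- neck + tl[["Neck-Head"]] * upm
  headtop <- head + tl[["Head-HeadTop"]] * upm

  latm <- matrix(lat, nf, 3, byrow = TRUE)
  fwdm <- matrix(fwd, nf, 3, byrow = TRUE)
  shoff <- tl[["Neck-LShoulder"]]
  shoL <- neck + shoff * latm
  shoR <- neck - shoff * latm
  phase <- pi * (kk - 1 + tau_all)
  armA <- 0.35                              # rad, arm swing amplitude
  thL <- armA * sin(phase)                  # left arm with right leg
  thR <- -thL
  arm <- function(sho, th) {
    elb <- sho + tl[["LShoulder-LElbow"]] * (sin(th) * fwdm - cos(th) * upm)
    wri <- elb + tl[["LElbow-LWrist"]] *
      (sin(th + 0.3) * fwdm - cos(th + 0.3) * upm)
    list(elb = elb, wri = wri)
  }
  armL <- arm(shoL, thL); armR <- arm(shoR, thR)

  heel_dir <- -cos(pi / 6) * fwdm - sin(pi / 6) * upm
  toe_dir <- cos(0.349) * fwdm - sin(0.349) * upm
  heelL <- ankL + tl[["LAnkle-LHeel"]] * heel_dir
  heelR <- ankR + tl[["RAnkle-RHeel"]] * heel_dir
  toeL <- ankL + tl[["LAnkle-LToe"]] * toe_dir
  toeR <- ankR + tl[["RAnkle-RToe"]] * toe_dir

  topo <- default_topology()
  a3 <- array(NA_real_, c(nf, 21, 3), dimnames = list(NULL, topo$joints, c("x", "y", "z")))
  put <- function(j, m) a3[, j, ] <<- m
  put("HeadTop", headtop); put("Head", head); put("Neck", neck)
  put("Chest", chest); put("Pelvis", pelvis)
  put("LShoulder", shoL); put("RShoulder", shoR)
  put("LElbow", armL$elb); put("RElbow", armR$elb)
  put("LWrist", armL$wri); put("RWrist", armR$wri)
  put("LHip", hipL); put("RHip", hipR)
  put("LKnee", kneeL); put("RKnee", kneeR)
  put("LAnkle", ankL); put("RAnkle", ankR)
  put("LHeel", heelL); put("RHeel", heelR)
  put("LToe", toeL); put("RToe", toeR)

  seq <- pose_sequence(frames3d = a3, fps = sc$fps,
                       subject = subject_meta(sc$subject_id, sc$height),
                       topology = topo)

  step_times <- diff(tk)
  pel_land <- (c(0, pk)[seq_len(n)] + pk) / 2   # pelvis axial at landing k
  speed_true <- (pel_land[n] - pel_land[1]) / (tk[n] - tk[1])
  truth <- structure(list(
    step_events = data.frame(time = tk, side = sides,
                             frame = as.integer(round(tk * sc$fps)),
                             stringsAsFactors = FALSE),
    step_lengths = Lk,
    step_times = step_times,
    true_averages = list(gait_speed = speed_true,
                         cadence = 60 / mean(step_times),
                         step_length_mean = 100 * mean(Lk),
                         step_time_mean = mean(step_times),
                         n_steps = n),
    camera_truth = camera,
    camera_distance = pelvis[, 3] - camera$position[3],
    walk_direction = fwd,
    scenario = sc), class = "gait_ground_truth")
  list(seq = seq, truth = truth)
}

#' Add seeded Gaussian estimation noise to 3D frames
#'
#' Emulates per-joint, per-frame monocular 3D estimation noise: i.i.d.
#' zero-mean Gaussian with SD `noise3d_sigma` on x and y and
#' `noise3d_sigma * depth_noise_factor` on z (depth is the least certain axis
#' in monocular reconstruction). Deterministic given the scenario seed; the
#' input sequence is left unmodified.
#'
#' @param seq A `pose_sequence` with `frames3d`.
#' @param scenario A [gait_scenario()] providing `noise3d_sigma`,
#'   `depth_noise_factor` and `seed`.
#' @return A new `pose_sequence`.
#' @export
add_noise3d <- function(seq, scenario) {
  stopifnot(inherits(seq, "pose_sequence"), !is.null(seq$frames3d))
  sig <- scenario$noise3d_sigma
  if (sig < 0) stop("noise3d_sigma must be >= 0")
  if (sig == 0) return(seq)
  a <- seq$frames3d
  d <- dim(a)
  noise <- with_seed(scenario$seed + 1L, {
    e <- array(stats::rnorm(prod(d), sd = sig), d)
    e[, , 3] <- e[, , 3] * scenario$depth_noise_factor
    e
  })
  seq$frames3d <- a + noise
  seq
}

#' Render noisy 2D keypoints from a 3D sequence
#'
#' Projects every frame through the (stationary) pinhole camera and adds
#' seeded Gaussian pixel noise, emulating a 2D keypoint detector.
#'
#' @param seq A `pose_sequence` with `frames3d`.
#' @param camera A [camera_model()].
#' @param noise2d_sigma Pixel noise SD (>= 0).
#' @param seed Integer seed.
#' @return The sequence with `frames2d` filled in.
#' @export
render_2d <- function(seq, camera, noise2d_sigma = 0, seed = 1L) {
  stopifnot(inherits(seq, "pose_sequence"), !is.null(seq$frames3d))
  if (noise2d_sigma < 0) stop("noise2d_sigma must be >= 0")
  a2 <- project_array(camera, seq$frames3d)
  if (noise2d_sigma > 0) {
    d <- dim(a2)
    a2 <- a2 + with_seed(seed, array(stats::rnorm(prod(d), sd = noise2d_sigma), d))
  }
  seq$frames2d <- a2
  seq
}
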