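#' Configuration of a synthetic validation study
#'
#' Mirrors the design of a walkway concurrent-validity study: a cohort of
#' subjects each completing several walks under a preferred-speed and a
#' fast-speed condition, recorded by the camera pipeline (system A) while a
#' gold-standard reference (system B, played by the simulator's ground
#' truth) measures the same walks.
#'
#' Population defaults reproduce the operating point of elderly walkers on
#' an instrumented walkway: preferred gait speed 1.42 (0.32) m/s, cadence
#' 121.77 (14.56) steps/min; the fast condition scales speed by 1.25 and
#' cadence by 1.12; within-subject trial-to-trial variation has a 2% CV.
#'
#' @param n_subjects Number of synthetic subjects (>= 2).
#' @param trials_per_condition Walks per subject per condition (>= 2).
#' @param noise3d_sigma Per-joint 3D noise SD (m); `0` for a noiseless study.
#' @param depth_noise_factor Depth-axis noise multiplier.
#' @param noise2d_sigma 2D keypoint noise SD (px).
#' @param n_steps,fps Walk geometry per trial.
#' @param use_optimizer Run the skeleton optimizer stage (skipped
#'   automatically when all noise is zero and it would be an exact identity).
#' @param optimizer An [optimizer_config()] or `NULL` for defaults matched
#'   to the simulator camera.
#' @param seed Study master seed (mandatory, drives everything).
#' @param out_dir Optional directory for per-trial CSVs, the report CSV and
#'   a run manifest.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_subjects = 43L, trials_per_condition = 3L,
                         noise3d_sigma = 0.02, depth_noise_factor = 2,
                         noise2d_sigma = 1, n_steps = 8L, fps = 30,
                         use_optimizer = TRUE, optimizer = NULL,
                         seed = 1L, out_dir = NULL) {
  stopifnot(n_subjects >= 2L, trials_per_condition >= 2L,
            noise3d_sigma >= 0, noise2d_sigma >= 0)
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_condition = as.integer(trials_per_condition),
                 noise3d_sigma = noise3d_sigma,
                 depth_noise_factor = depth_noise_factor,
                 noise2d_sigma = noise2d_sigma,
                 n_steps = as.integer(n_steps), fps = fps,
                 use_optimizer = use_optimizer, optimizer = optimizer,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "study_config")
}

# draw one subject's anthropometrics and preferred-condition gait
draw_subject <- function() {
  height <- clamp(stats::rnorm(1, 1.70, 0.09), 1.50, 1.95)
  speed <- clamp(stats::rnorm(1, 1.42, 0.32), 0.70, 2.00)
  cadence <- clamp(stats::rnorm(1, 121.77, 14.56), 90, 150)
  # keep the implied step length within the leg reach of this stature
  lmax <- 0.52 * height
  if (60 * speed / cadence > lmax) cadence <- 60 * speed / lmax
  list(height = height, speed = speed, cadence = cadence)
}

#' Run a full synthetic validation study
#'
#' For every subject, condition and trial: generates a ground-truthed walk,
#' corrupts it with 3D estimation noise and renders noisy 2D keypoints,
#' optimizes the skeleton, detects steps and computes the four gait
#' parameters. The per-walk pipeline estimates form system A; the
#' simulator's exact per-walk truth forms the reference system B. A
#' Table-style agreement report over all walks is produced via
#' [validity_report()]. Fully deterministic given the config seed. A failing
#' trial is logged and skipped; if more than 20% of trials fail the study
#' aborts.
#'
#' @param config A [study_config()].
#' @param verbose Print per-subject progress.
#' @return A list of class `study_result`: `report` (agreement_report),
#'   `trials` (long data.frame: subject, condition, trial, parameter,
#'   estimate, truth), `n_failed`, `manifest`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  conditions <- list(preferred = c(speed = 1, cadence = 1),
                     fast = c(speed = 1.25, cadence = 1.12))
  subjects <- with_seed(config$seed,
                        lapply(seq_len(config$n_subjects),
                               function(i) draw_subject()))
  rows <- list()
  n_failed <- 0L; n_total <- 0L
  for (si in seq_len(config$n_subjects)) {
    sub <- subjects[[si]]
    if (verbose) message("subject ", si, "/", config$n_subjects)
    for (ci in seq_along(conditions)) {
      cnd <- names(conditions)[ci]
      mult <- conditions[[ci]]
      for (ti in seq_len(config$trials_per_condition)) {
        n_total <- n_total + 1L
        trial_seed <- config$seed + si * 997L + ci * 101L + ti
        jit <- with_seed(trial_seed, stats::rnorm(2, 1, 0.02))
        est <- tryCatch(
          run_trial(speed = sub$speed * mult[["speed"]] * jit[1],
                    cadence = sub$cadence * mult[["cadence"]] * jit[2],
                    height = sub$height, config = config,
                    trial_seed = trial_seed,
                    subject_id = sprintf("S%02d", si)),
          error = function(e) {
            message("trial failed (subject ", si, ", ", cnd, " ", ti, "): ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(est)) { n_failed <- n_failed + 1L; next }
        for (p in names(est$estimate))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sprintf("S%02d", si), condition = cnd, trial = ti,
            parameter = p, estimate = est$estimate[[p]],
            truth = est$truth[[p]], stringsAsFactors = FALSE)
      }
    }
  }
  if (n_failed > 0.2 * n_total)
    stop("study failed: ", n_failed, " of ", n_total, " trials unusable")
  trials <- do.call(rbind, rows)
  long <- function(col) data.frame(subject = trials$subject,
                                   condition = trials$condition,
                                   trial = trials$trial,
                                   parameter = trials$parameter,
                                   value = trials[[col]],
                                   stringsAsFactors = FALSE)
  report <- validity_report(long("estimate"), long("truth"),
                            seed = config$seed)
  manifest <- list(config = unclass(config[setdiff(names(config), "optimizer")]),
                   package_version = as.character(utils::packageVersion("gaitmetrics")),
                   n_trials = n_total, n_failed = n_failed)
  res <- structure(list(report = report, trials = trials,
                        n_failed = n_failed, manifest = manifest),
                   class = "study_result")
  if (!is.null(config$out_dir)) write_study(res, config$out_dir)
  res
}

# one synthetic walk through the full pipeline; returns estimate + truth
run_trial <- function(speed, cadence, height, config, trial_seed, subject_id) {
  sc <- gait_scenario(gait_speed = speed, cadence = cadence,
                      n_steps = config$n_steps, fps = config$fps,
                      noise3d_sigma = config$noise3d_sigma,
                      depth_noise_factor = config$depth_noise_factor,
                      noise2d_sigma = config$noise2d_sigma,
                      height = height, subject_id = subject_id,
                      seed = trial_seed)
  w <- generate_walk(sc)
  cam <- w$truth$camera_truth
  noisy <- add_noise3d(w$seq, sc)
  # the 2D detector observes the video, not the 3D lifter's errors: render
  # from the clean walk with independent pixel noise
  r2 <- render_2d(w$seq, cam, sc$noise2d_sigma, seed = trial_seed + 1L)
  noisy$frames2d <- r2$frames2d
  analyzed <- if (config$use_optimizer &&
                  (sc$noise3d_sigma > 0 || sc$noise2d_sigma > 0)) {
    ocfg <- config$optimizer
    if (is.null(ocfg))
      ocfg <- optimizer_config(focal = cam$focal,
                               principal_point = cam$principal_point)
    optimize_sequence(noisy, noisy, height, ocfg)$seq
  } else noisy
  gp <- analyze_gait(analyzed)
  ta <- w$truth$true_averages
  list(estimate = list(gait_speed = gp$gait_speed, cadence = gp$cadence,
                       step_length = gp$step_length_mean,
                       step_time = gp$step_time_mean),
       truth = list(gait_speed = ta$gait_speed, cadence = ta$cadence,
                    step_length = ta$step_length_mean,
                    step_time = ta$step_time_mean))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d walk-parameter rows, %d failed trials\n",
              nrow(x$trials), x$n_failed))
  print(x$report)
  invisible(x)
}

# write per-trial CSV, report CSV and manifest JSON
write_study <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$report),
                   file.path(out_dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
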