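# Shared fixture builders (everything is generated in code; no stored data).

# a clean regular walk at the default operating point
clean_walk <- function(n_steps = 6, fps = 30, speed = NULL, cadence = 120,
                       step_length = 0.70, seed = 1, cv = 0, ...) {
  sc <- gait_scenario(gait_speed = speed, cadence = cadence,
                      step_length = step_length, n_steps = n_steps,
                      fps = fps, step_time_cv = cv, step_length_cv = cv,
                      seed = seed, ...)
  generate_walk(sc)
}

# a noisy walk with 2D rendered from the clean sequence (the 2D detector
# watches the video, independently of the 3D lifter's errors)
noisy_walk <- function(sigma = 0.02, px = 1, seed = 1, n_steps = 8,
                       fps = 30, speed = 1.42, cadence = 121.77, ...) {
  sc <- gait_scenario(gait_speed = speed, cadence = cadence,
                      n_steps = n_steps, fps = fps, noise3d_sigma = sigma,
                      noise2d_sigma = px, seed = seed, ...)
  w <- generate_walk(sc)
  noisy <- add_noise3d(w$seq, sc)
  noisy$frames2d <- render_2d(w$seq, w$truth$camera_truth, px,
                              seed = seed + 5000L)$frames2d
  list(noisy = noisy, clean = w$seq, truth = w$truth, scenario = sc)
}

default_cam_config <- function(camera, ...)
  optimizer_config(focal = camera$focal,
                   principal_point = camera$principal_point, ...)

mean_joint_error <- function(a3, ref3) {
  mean(sqrt(rowSums(matrix((a3 - ref3)^2, ncol = 3))))
}

rel_err_pct <- function(est, truth) abs(est - truth) / abs(truth) * 100

# the four parameter errors (%) of a gait_parameters object vs ground truth
param_errors <- function(gp, truth) {
  ta <- truth$true_averages
  c(gait_speed = rel_err_pct(gp$gait_speed, ta$gait_speed),
    cadence = rel_err_pct(gp$cadence, ta$cadence),
    step_length = rel_err_pct(gp$step_length_mean, ta$step_length_mean),
    step_time = rel_err_pct(gp$step_time_mean, ta$step_time_mean))
}
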