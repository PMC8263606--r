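test_that("the speed/cadence/step-length triple closes and detects inconsistency", {
  expect_equal(resolve_gait_triple(cadence = 120, step_length = 0.70)$gait_speed,
               1.40)
  # closed form at the walkway operating point
  tri <- resolve_gait_triple(gait_speed = 1.42, cadence = 121.77)
  expect_equal(tri$step_length, 60 * 1.42 / 121.77, tolerance = 1e-12)
  expect_equal(round(tri$step_length, 4), 0.6997)
  expect_error(resolve_gait_triple(gait_speed = 1.40, cadence = 120,
                                   step_length = 0.60), "inconsistent")
  expect_error(resolve_gait_triple(gait_speed = 1.40), "at least two")
  sc <- gait_scenario(step_length = 0.70, cadence = 120)
  expect_equal(sc$gait_speed, sc$step_length * sc$cadence / 60,
               tolerance = 1e-9)
})

test_that("scenario validation rejects bad dispersions, fps and step counts", {
  expect_error(gait_scenario(step_length = 0.7, cadence = 120, n_steps = 1),
               "n_steps")
  expect_error(gait_scenario(step_length = 0.7, cadence = 120, fps = 5), "fps")
  expect_error(gait_scenario(step_length = 0.7, cadence = 120,
                             step_time_cv = -0.1), ">= 0")
  expect_error(gait_scenario(step_length = 0.7, cadence = 120,
                             depth_noise_factor = 0.5), "depth_noise_factor")
})

test_that("a noiseless regular walk realizes its scenario exactly", {
  w <- clean_walk(n_steps = 6, step_length = 0.70, cadence = 120)
  tr <- w$truth
  # the true averages are the identity triple
  expect_equal(tr$true_averages$gait_speed, 1.40, tolerance = 1e-9)
  expect_equal(tr$true_averages$cadence, 120, tolerance = 1e-9)
  expect_equal(tr$true_averages$step_length_mean, 70.0, tolerance = 1e-9)
  expect_equal(tr$true_averages$step_time_mean, 0.500, tolerance = 1e-9)
  # at each true landing instant the inter-ankle gap along the walk
  # direction equals the step length
  gap <- (w$seq$frames3d[, "LAnkle", ] - w$seq$frames3d[, "RAnkle", ]) %*%
    tr$walk_direction
  expect_equal(unname(abs(gap[tr$step_events$frame + 1L, 1])),
               rep(0.70, 6), tolerance = 1e-6)
  # sides alternate; step times diff the event times
  expect_true(all(tr$step_events$side[-1] != tr$step_events$side[-6]))
  expect_equal(tr$step_times, diff(tr$step_events$time), tolerance = 1e-9)
})

test_that("generation is deterministic given the seed", {
  sc <- gait_scenario(step_length = 0.70, cadence = 115, n_steps = 5,
                      step_time_cv = 0.05, step_length_cv = 0.05, seed = 42)
  w1 <- generate_walk(sc)
  w2 <- generate_walk(sc)
  expect_identical(w1$seq$frames3d, w2$seq$frames3d)
  expect_identical(w1$truth$step_events, w2$truth$step_events)
})

test_that("bone lengths are conserved and stance feet are ground-fixed", {
  w <- clean_walk(n_steps = 5, seed = 2, cv = 0.04)
  tl <- target_bone_lengths(1.70)
  for (i in seq(1, n_frames(w$seq), by = 7)) {
    bl <- bone_lengths(w$seq$frames3d[i, , ])
    expect_lt(max(abs(bl - tl[names(bl)])), 1e-9)
  }
  # during each stance the grounded ankle does not move: the foot landing
  # at step k is stance until the next landing (frames strictly inside the
  # true landing times)
  ev <- w$truth$step_events
  for (k in 1:(nrow(ev) - 1)) {
    ank <- paste0(ev$side[k], "Ankle")   # the foot that just landed
    fr <- (ceiling(ev$time[k] * 30) + 1L):(floor(ev$time[k + 1L] * 30) + 1L)
    seg <- w$seq$frames3d[fr, ank, ]
    expect_lt(max(dist(seg)), 1e-9)
  }
})

test_that("the noiseless distance signal has one maximum per step and minima between them", {
  for (n_steps in c(4, 7)) {
    w <- clean_walk(n_steps = n_steps, seed = 1)
    d <- foot_distance_signal(w$seq)$d
    r <- rle(d)
    v <- r$values; m <- length(v)
    kinds <- sapply(2:(m - 1), function(i) {
      if (v[i] > v[i - 1] && v[i] > v[i + 1]) "max"
      else if (v[i] < v[i - 1] && v[i] < v[i + 1]) "min" else NA
    })
    expect_equal(sum(kinds == "max", na.rm = TRUE), n_steps)
    expect_equal(sum(kinds == "min", na.rm = TRUE), n_steps - 1L)
    # maxima coincide with the true landings within half a frame
    ends <- cumsum(r$lengths)
    maxfr <- ends[which(!is.na(kinds) & kinds == "max") + 1L] - 1L
    expect_lte(max(abs(maxfr - w$truth$step_events$frame)), 1L)
  }
})

test_that("3D noise has the requested per-axis magnitudes and respects the seed", {
  sc <- gait_scenario(step_length = 0.7, cadence = 120, n_steps = 20,
                      noise3d_sigma = 0.02, depth_noise_factor = 2, seed = 8)
  w <- generate_walk(sc)
  expect_identical(add_noise3d(w$seq, gait_scenario(step_length = 0.7,
    cadence = 120, n_steps = 20, seed = 8))$frames3d, w$seq$frames3d)
  noisy <- add_noise3d(w$seq, sc)
  delta <- noisy$frames3d - w$seq$frames3d
  # law of large numbers: empirical SDs within 5% (> 6000 joint-frames)
  expect_gt(length(delta[, , 1]), 6000)
  expect_equal(stats::sd(delta[, , 1]), 0.02, tolerance = 0.05)
  expect_equal(stats::sd(delta[, , 2]), 0.02, tolerance = 0.05)
  expect_equal(stats::sd(delta[, , 3]), 0.04, tolerance = 0.05)
  # same scenario -> identical noise; different seed -> different noise
  expect_identical(add_noise3d(w$seq, sc)$frames3d, noisy$frames3d)
  sc2 <- sc; sc2$seed <- 9L
  noisy2 <- add_noise3d(w$seq, sc2)
  expect_false(identical(noisy2$frames3d, noisy$frames3d))
  expect_equal(stats::sd(noisy2$frames3d[, , 3] - w$seq$frames3d[, , 3]),
               0.04, tolerance = 0.05)
})

test_that("2D rendering matches per-frame projection and grows as the subject approaches", {
  w <- clean_walk(n_steps = 6, seed = 4)
  cam <- w$truth$camera_truth
  seq <- render_2d(w$seq, cam, 0)
  # zero noise: every frame equals project_frame exactly
  for (i in c(1, 25, n_frames(seq)))
    expect_equal(seq$frames2d[i, , ], project_frame(cam, w$seq$frames3d[i, , ]),
                 tolerance = 1e-12)
  # oracle: recompute projections independently; the mean absolute
  # inter-ankle pixel separation grows from the first to the last third
  pix_sep <- sapply(seq_len(n_frames(seq)), function(i) {
    pr <- project_frame(cam, w$seq$frames3d[i, , ])
    sqrt(sum((pr["LAnkle", ] - pr["RAnkle", ])^2))
  })
  n <- length(pix_sep)
  expect_gt(mean(pix_sep[(2 * n / 3):n]), mean(pix_sep[1:(n / 3)]))
  # seeded pixel noise is reproducible
  s1 <- render_2d(w$seq, cam, 2, seed = 7)
  s2 <- render_2d(w$seq, cam, 2, seed = 7)
  expect_identical(s1$frames2d, s2$frames2d)
  # pathological scenario: subject behind the camera errors
  back <- w$seq
  back$frames3d[, , 3] <- back$frames3d[, , 3] - 20
  expect_error(render_2d(back, cam, 0), "behind")
})

test_that("an optional double-support dwell produces distance plateaus at the landings", {
  w <- clean_walk(n_steps = 5, cadence = 100, dwell = 2 / 30)
  d <- foot_distance_signal(w$seq)$d
  ev <- w$truth$step_events
  for (k in 2:4) {
    fr <- ev$frame[k] + 1L
    expect_lt(diff(range(d[fr:(fr + 2L)])), 1e-9)  # flat for the dwell
  }
})
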