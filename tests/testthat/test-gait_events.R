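make_signal <- function(d, fps = 30) {
  structure(list(t = (seq_along(d) - 1) / fps, d = d, fps = fps,
                 mode = "ankle-to-ankle"), class = "distance_signal")
}

test_that("the foot distance signal measures ankle separation and both modes coincide", {
  topo <- default_topology()
  n <- 10
  a3 <- array(0, c(n, 21, 3), dimnames = list(NULL, topo$joints, c("x", "y", "z")))
  a3[, "LAnkle", 1] <- 0.35; a3[, "RAnkle", 1] <- -0.35
  a3[, "LAnkle", 2] <- 0.1; a3[, "RAnkle", 2] <- 0.1
  a3[, , 3] <- 5
  seq <- pose_sequence(frames3d = a3, fps = 30,
                       subject = subject_meta("s", 1.7))
  sig <- foot_distance_signal(seq)
  expect_equal(sig$d, rep(0.70, n))
  ref <- foot_distance_signal(seq, "foot-to-reference-joint",
                              foot = "LAnkle", reference = "RAnkle")
  expect_equal(ref$d, sig$d)
  # a missing ankle names the frame
  a3[4, "LAnkle", 1] <- NA
  seq2 <- pose_sequence(frames3d = a3, fps = 30,
                        subject = subject_meta("s", 1.7))
  expect_error(foot_distance_signal(seq2), "frame 3")
})

test_that("noiseless walk maxima equal the step length up to frame quantization", {
  w <- clean_walk(n_steps = 6, step_length = 0.70, cadence = 120)
  sig <- foot_distance_signal(w$seq)
  cand <- extrema_candidates(sig)
  mx <- cand$value[cand$kind == "max"]
  # 3D ankle distance includes the lateral stance width (0.10 m default)
  expect_equal(mx, rep(sqrt(0.70^2 + 0.10^2), 6), tolerance = 1e-3)
})

test_that("zero-phase smoothing preserves constants, passes the gait band, and suppresses noise", {
  const <- make_signal(rep(0.5, 90))
  expect_lt(max(abs(smooth_signal(const, 6)$d - const$d)), 1e-5)
  expect_error(smooth_signal(const, 15), "Nyquist")
  # 1 Hz sinusoid through a 5 Hz low-pass keeps its amplitude within 2%
  t <- (0:299) / 30
  sine <- make_signal(0.35 + 0.34 * cos(2 * pi * 1 * t))
  sm <- smooth_signal(sine, 5)
  mid <- 60:240                       # away from the edges
  expect_equal(max(sm$d[mid]) - min(sm$d[mid]), 2 * 0.34, tolerance = 0.02)
  # 12 Hz interference (well above the 6 Hz cutoff) is attenuated >= 5x
  hf <- 0.05 * sin(2 * pi * 12 * t)
  noisy <- make_signal(sine$d + hf)
  sm2 <- smooth_signal(noisy, 6)
  expect_lt(sqrt(mean((sm2$d[mid] - sine$d[mid])^2)),
            sqrt(mean((noisy$d[mid] - sine$d[mid])^2)) / 5)
})

test_that("extremum candidates equal the literal neighbor-comparison definition", {
  # analytic sinusoid: maxima every 0.5 s starting at t = 0
  t <- (0:89) / 30
  sig <- make_signal(0.35 + 0.34 * cos(2 * pi * t / 0.5))
  cand <- extrema_candidates(sig)
  mx <- cand$frame[cand$kind == "max"]
  expect_equal(mx, c(15, 30, 45, 60, 75))
  mn <- cand$frame[cand$kind == "min"]
  expect_true(all(mn %in% c(7, 8, 22, 23, 37, 38, 52, 53, 67, 68, 82, 83)))
  # strictly monotone: no interior candidates
  expect_equal(nrow(extrema_candidates(make_signal(seq(0, 1, length.out = 50)))),
               0L)
  expect_error(extrema_candidates(make_signal(c(1, 2))), "3 samples")
  # oracle: brute-force sample-wise scan on a noisy simulated signal
  nw <- noisy_walk(sigma = 0.02, seed = 3)
  sig <- smooth_signal(foot_distance_signal(nw$noisy))
  cand <- extrema_candidates(sig)
  d <- sig$d; n <- length(d)
  for (r in seq_len(nrow(cand))) {
    i <- cand$frame[r] + 1L
    if (cand$kind[r] == "max") {
      expect_gte(d[i], d[max(1, i - 1)]); expect_gte(d[i], d[min(n, i + 1)])
    } else {
      expect_lte(d[i], d[max(1, i - 1)]); expect_lte(d[i], d[min(n, i + 1)])
    }
  }
  # plateau runs emit candidates at the run endpoints
  plat <- make_signal(c(0, 1, 2, 3, 3, 3, 2, 1, 0, 1, 2))
  pc <- extrema_candidates(plat)
  expect_equal(pc$frame[pc$kind == "max"], c(3, 5))
  expect_equal(pc$frame[pc$kind == "min"], 8)
})

test_that("honest extrema apply the tie rule and leave clean signals untouched", {
  # an equal-valued plateau of maxima resolves to its earliest frame
  d <- c(seq(0, 1, length.out = 15), 1, seq(1, 0, length.out = 15),
         seq(0, 1, length.out = 15), seq(1, 0, length.out = 16))
  sig <- make_signal(d)
  cand <- extrema_candidates(sig)
  expect_true(all(c(14, 16) %in% cand$frame[cand$kind == "max"]))
  hon <- honest_extrema(cand, sig, window_s = 0.25)
  first_max <- hon$frame[hon$kind == "max"][1]
  expect_equal(first_max, 14)
  # clean sinusoid: honest extrema are exactly the candidates (after
  # trimming to a max...max span)
  t <- (0:89) / 30
  sig2 <- make_signal(0.35 + 0.34 * cos(2 * pi * t / 0.5))
  cand2 <- extrema_candidates(sig2)
  hon2 <- honest_extrema(cand2, sig2)
  expect_equal(hon2$frame[hon2$kind == "max"], c(15, 30, 45, 60, 75))
  expect_true(all(hon2$kind == rep(c("max", "min"), length.out = nrow(hon2))))
  expect_error(honest_extrema(cand2[0, ], sig2), "insufficient")
})

test_that("honest maxima match ground-truth landings under dwell and noise", {
  # a 2-frame double-support dwell forms a plateau; the smoothed peak sits
  # at the plateau center plus the kernel spread, so the localization bound
  # is the plateau width plus ~2 frames (computed over seeds 1-20, worst 4)
  for (seed in 1:5) {
    sc <- gait_scenario(gait_speed = 1.35, cadence = 115, n_steps = 7,
                        dwell = 2 / 30, noise3d_sigma = 0.02, seed = seed)
    w <- generate_walk(sc)
    noisy <- add_noise3d(w$seq, sc)
    sig <- smooth_signal(foot_distance_signal(noisy))
    hon <- honest_extrema(extrema_candidates(sig), sig)
    mx <- hon$frame[hon$kind == "max"]
    expect_equal(length(mx), 7L)
    expect_lte(max(abs(mx - w$truth$step_events$frame)), 4L)
  }
})

test_that("candidate partition: every honest extremum is a candidate and clusters do not overlap", {
  nw <- noisy_walk(sigma = 0.02, seed = 9)
  sig <- smooth_signal(foot_distance_signal(nw$noisy))
  cand <- extrema_candidates(sig)
  hon <- honest_extrema(cand, sig)
  expect_true(all(hon$frame %in% cand$frame))
  for (kind in c("max", "min")) {
    mem <- unlist(hon$members[hon$kind == kind])
    expect_equal(anyDuplicated(mem), 0L)
    expect_true(all(mem %in% cand$frame[cand$kind == kind]))
  }
  # representatives belong to their own cluster; alternation holds
  expect_true(all(mapply(function(f, m) f %in% m, hon$frame, hon$members)))
  expect_true(all(hon$kind[-1] != hon$kind[-nrow(hon)]))
})

test_that("steps are segmented with alternating sides and half-second intervals", {
  w <- clean_walk(n_steps = 6, step_length = 0.70, cadence = 120)
  sig_raw <- foot_distance_signal(w$seq)
  sig <- smooth_signal(sig_raw)
  hon <- honest_extrema(extrema_candidates(sig), sig)
  ev <- segment_steps(hon, w$seq, sig_raw)
  expect_equal(nrow(ev), 6L)
  expect_true(all(ev$side[-1] != ev$side[-6]))
  expect_equal(ev$side, w$truth$step_events$side)
  expect_equal(ev$interval_to_next[1:5], rep(0.5, 5), tolerance = 0.01)
  expect_true(is.na(ev$interval_to_next[6]))
  expect_true(all(diff(ev$landing_frame) > 0))
})

test_that("side assignment agrees with ground truth in at least 90% of noisy steps", {
  agree <- 0; total <- 0
  for (seed in 1:20) {
    nw <- noisy_walk(sigma = 0.02, seed = seed, n_steps = 7)
    sig_raw <- foot_distance_signal(nw$noisy)
    sig <- smooth_signal(sig_raw)
    hon <- honest_extrema(extrema_candidates(sig), sig)
    ev <- segment_steps(hon, nw$noisy, sig_raw)
    tru <- nw$truth$step_events
    m <- min(nrow(ev), nrow(tru))
    # match detected landings to the nearest true landing
    for (i in seq_len(nrow(ev))) {
      k <- which.min(abs(tru$frame - ev$landing_frame[i]))
      agree <- agree + (ev$side[i] == tru$side[k]); total <- total + 1
    }
  }
  expect_gte(agree / total, 0.9)
})

test_that("step period estimation recovers the cadence", {
  w <- clean_walk(n_steps = 8, cadence = 120)
  sig <- smooth_signal(foot_distance_signal(w$seq))
  expect_equal(estimate_step_period(sig), 0.5, tolerance = 0.1)
})
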