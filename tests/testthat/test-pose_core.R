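test_that("canonical topology is a 21-joint tree with a consistent mirror map", {
  topo <- default_topology()
  expect_true(check_topology(topo))
  expect_length(topo$joints, 21L)
  expect_equal(nrow(topo$bones), 20L)
  # mirror is an involution; midline joints are fixed points
  expect_identical(unname(topo$mirror[unname(topo$mirror)]),
                   names(topo$mirror))
  for (j in c("HeadTop", "Head", "Neck", "Chest", "Pelvis"))
    expect_identical(unname(topo$mirror[j]), j)
  expect_identical(unname(topo$mirror["LAnkle"]), "RAnkle")
})

test_that("target bone lengths scale linearly, are symmetric, and the vertical chain sums to the declared stature fraction", {
  tab <- anthropometry_table()
  tl1 <- target_bone_lengths(1.80)
  expect_equal(unname(tl1["LHip-LKnee"]), 1.80 * tab$fractions[["LHip-LKnee"]])
  # homogeneity: doubling height doubles every bone
  expect_equal(target_bone_lengths(2.40) / 2, target_bone_lengths(1.20),
               tolerance = 1e-12)
  # left/right symmetry exact
  expect_identical(unname(tl1["LHip-LKnee"]), unname(tl1["RHip-RKnee"]))
  expect_identical(unname(tl1["LAnkle-LToe"]), unname(tl1["RAnkle-RToe"]))
  # vertical chain sums to height * stature fraction (oracle: sum fractions)
  tl <- target_bone_lengths(1.70)
  chain_sum <- sum(tl[tab$vertical_chain])
  expect_equal(chain_sum, 1.70 * tab$stature_fraction, tolerance = 1e-12)
  expect_error(target_bone_lengths(0.4), "height")
  expect_error(target_bone_lengths(3.0), "height")
})

test_that("bone lengths measure Euclidean distances and omit missing endpoints", {
  topo <- default_topology()
  fr <- matrix(NA_real_, 21, 3, dimnames = list(topo$joints, c("x", "y", "z")))
  fr["LHip", ] <- c(2.1, 1.4, 6.0)
  fr["LKnee", ] <- c(2.1, 0.9, 6.0)
  bl <- bone_lengths(fr, topo)
  expect_equal(unname(bl["LHip-LKnee"]), 0.5)
  expect_false("LKnee-LAnkle" %in% names(bl))  # missing ankle: omitted
  fr["LKnee", ] <- fr["LHip", ]
  expect_equal(unname(bone_lengths(fr, topo)["LHip-LKnee"]), 0)
  # frames from the generator match the anthropometric table to 1e-9
  w <- clean_walk(n_steps = 4)
  tl <- target_bone_lengths(1.70)
  for (i in c(1, 10, n_frames(w$seq))) {
    bl <- bone_lengths(w$seq$frames3d[i, , ])
    expect_lt(max(abs(bl - tl[names(bl)])), 1e-9)
  }
})

test_that("pinhole projection obeys the principal point, the 1/z law, and a per-joint oracle", {
  cam <- camera_model(1000, c(500, 900), c(0, 1.0, 0))
  topo <- default_topology()
  fr <- matrix(NA_real_, 21, 3, dimnames = list(topo$joints, c("x", "y", "z")))
  fr["Pelvis", ] <- c(0, 1.0, 4)        # on the optical axis
  fr["Neck", ] <- c(0.2, 1.5, 4)
  pr <- project_frame(cam, fr)
  expect_equal(unname(pr["Pelvis", ]), c(500, 900))
  # doubling depth halves the pixel offset from the principal point
  fr2 <- fr; fr2[, 3] <- 2 * (fr[, 3] - 0) # depth doubled relative to camera
  pr2 <- project_frame(cam, fr2)
  expect_equal(unname(pr2["Neck", ] - c(500, 900)),
               unname(pr["Neck", ] - c(500, 900)) / 2, tolerance = 1e-12)
  # brute-force per-joint oracle on a full synthetic frame
  w <- clean_walk(n_steps = 4)
  cam <- w$truth$camera_truth
  fr <- w$seq$frames3d[7, , ]
  pr <- project_frame(cam, fr)
  for (j in rownames(fr)) {
    rel <- fr[j, ] - cam$position
    expect_equal(unname(pr[j, 1]),
                 cam$principal_point[1] + cam$focal * rel[[1]] / rel[[3]],
                 tolerance = 1e-9)
    expect_equal(unname(pr[j, 2]),
                 cam$principal_point[2] - cam$focal * rel[[2]] / rel[[3]],
                 tolerance = 1e-9)
  }
  # a joint behind the camera is an error naming the joint
  fr["LWrist", 3] <- cam$position[3] - 1
  expect_error(project_frame(cam, fr), "LWrist")
})

test_that("pose JSON round-trips exactly, preserves missingness, and rejects invalid files", {
  w <- clean_walk(n_steps = 4, seed = 3)
  seq <- render_2d(w$seq, w$truth$camera_truth, 0.5, seed = 9)
  # knock out some joints in both channels
  seq$frames2d[3, "LWrist", ] <- NA
  seq$frames3d[5, "RElbow", ] <- NA
  path <- withr::local_tempfile(fileext = ".json")
  write_pose_sequence(seq, path)
  back <- read_pose_sequence(path, "pose-json-combined")
  expect_equal(back$frames3d, seq$frames3d)
  expect_equal(back$frames2d, seq$frames2d)
  expect_equal(back$fps, seq$fps)
  expect_equal(back$subject$height, seq$subject$height)
  expect_true(all(is.na(back$frames2d[3, "LWrist", ])))
  expect_true(all(is.na(back$frames3d[5, "RElbow", ])))
  # refuse to write an invalid sequence
  bad <- seq; bad$fps <- 0
  expect_error(write_pose_sequence(bad, path), "fps")
})

test_that("pose JSON reader maps detector joint aliases and reports malformed frames", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- list(meta = list(fps = 30, height_m = 1.7, subject_id = "p1"),
              frames = list(list(joints2d = list(
                "Neck" = list(x = 150, y = 50),
                "Left Hip" = list(x = 170, y = 600),
                "Left Ankle" = list(x = 175, y = 1000)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  seq <- read_pose_sequence(path, "pose-json-2d")
  expect_equal(unname(seq$frames2d[1, "Neck", ]), c(150, 50))
  expect_equal(unname(seq$frames2d[1, "LHip", ]), c(170, 600))
  expect_equal(unname(seq$frames2d[1, "LAnkle", ]), c(175, 1000))
  # 3D sample with metric coordinates
  doc3 <- list(meta = list(fps = 30, height_m = 1.7),
               frames = list(list(joints3d = list(
                 "Neck" = list(x = 2.5, y = 1.9, z = 6.0),
                 "Left Hip" = list(x = 2.1, y = 1.4, z = 6.0),
                 "Left Ankle" = list(x = 2.4, y = 0.12, z = 6.0)))))
  jsonlite::write_json(doc3, path, auto_unbox = TRUE)
  seq3 <- read_pose_sequence(path, "pose-json-3d")
  expect_equal(unname(seq3$frames3d[1, "Neck", ]), c(2.5, 1.9, 6.0))
  expect_equal(unname(seq3$frames3d[1, "LAnkle", ]), c(2.4, 0.12, 6.0))
  # unknown joint name names the frame; empty frame list refuses
  doc$frames[[1]]$joints2d[["Shin"]] <- list(x = 1, y = 2)
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_pose_sequence(path, "pose-json-2d"), "frame 0.*Shin")
  jsonlite::write_json(list(meta = list(fps = 30, height_m = 1.7),
                            frames = list()), path, auto_unbox = TRUE)
  expect_error(read_pose_sequence(path), "no frames")
  jsonlite::write_json(list(meta = list(fps = 30),
                            frames = doc$frames), path, auto_unbox = TRUE)
  expect_error(read_pose_sequence(path), "height_m|configuration")
})

test_that("round-trip identity holds for randomized sequences in all dialects", {
  for (seed in 1:3) {
    w <- clean_walk(n_steps = 3, seed = seed, cv = 0.05)
    seq <- render_2d(w$seq, w$truth$camera_truth, 1, seed = seed)
    path <- withr::local_tempfile(fileext = ".json")
    write_pose_sequence(seq, path)
    back <- read_pose_sequence(path, "pose-json-combined")
    expect_equal(back$frames3d, seq$frames3d)
    expect_equal(back$frames2d, seq$frames2d)
    # 3d-only dialect
    seq3 <- seq; seq3$frames2d <- NULL
    write_pose_sequence(seq3, path)
    expect_equal(read_pose_sequence(path, "pose-json-3d")$frames3d,
                 seq$frames3d)
  }
})

test_that("validate_sequence reports exactly the injected violations", {
  w <- clean_walk(n_steps = 4)
  expect_equal(nrow(validate_sequence(w$seq)), 0L)
  seq <- w$seq
  seq$frames3d[4, "LKnee", 2] <- NaN
  rep <- validate_sequence(seq)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$frame, 3L)           # 0-based
  expect_equal(rep$joint, "LKnee")
  # 2d/3d length mismatch
  seq2 <- render_2d(w$seq, w$truth$camera_truth, 0)
  seq2$frames2d <- seq2$frames2d[1:5, , , drop = FALSE]
  expect_true(any(grepl("mismatch", validate_sequence(seq2)$issue)))
})

test_that("data-frame export is one row per frame-joint with both channels", {
  w <- clean_walk(n_steps = 3)
  seq <- render_2d(w$seq, w$truth$camera_truth, 0)
  df <- as.data.frame(seq)
  expect_equal(nrow(df), n_frames(seq) * 21L)
  expect_named(df, c("frame", "t_s", "joint", "u_px", "v_px",
                     "x_m", "y_m", "z_m"))
  i <- which(df$frame == 2 & df$joint == "LAnkle")
  expect_equal(df$x_m[i], unname(seq$frames3d[3, "LAnkle", 1]))
  expect_equal(df$u_px[i], unname(seq$frames2d[3, "LAnkle", 1]))
})
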