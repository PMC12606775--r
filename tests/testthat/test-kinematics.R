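test_that("cardan composition and decomposition round-trip", {
  expect_equal(as.numeric(cardan_xyz(diag(3))), c(0, 0, 0))
  expect_equal(as.numeric(cardan_xyz(cardan_rotation(c(10, 0, 0)))),
               c(10, 0, 0), tolerance = 1e-12)
  set.seed(42)
  err <- replicate(1000, {
    ang <- stats::runif(3, -30, 30)
    max(abs(as.numeric(cardan_xyz(cardan_rotation(ang))) - ang))
  })
  expect_lt(max(err), 1e-9)
  expect_error(cardan_xyz(matrix(1, 3, 3)), "not a rotation")
  expect_true(attr(cardan_xyz(cardan_rotation(c(0, 88, 0))), "gimbal"))
})

test_that("segment frames are orthonormal and flag degenerate frames", {
  s <- generate_session(duration = 5, seed = 9, noise = quiet_noise())
  mk <- s$trials$TM$markers
  fr <- build_segment_frames(mk)
  expect_true(all(fr$valid))
  for (seg in c("cranial", "caudal", "reference", "pelvis")) {
    R <- fr[[seg]][, , 10]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
  # virtual marker is exactly 20 mm from S3
  d <- sqrt(rowSums((fr$virtual_s3 - aquagait:::marker_xyz(mk, "S3"))^2))
  expect_equal(range(d), c(20, 20), tolerance = 1e-9)
  # coincident points invalidate the frame
  mk2 <- mk
  mk2[5, c("T5_x", "T5_y", "T5_z")] <- mk2[5, c("L1_x", "L1_y", "L1_z")]
  fr2 <- build_segment_frames(mk2)
  expect_false(fr2$valid[5])
})

test_that("pelvic frame is exactly equivariant under rigid rotation", {
  s <- generate_session(duration = 5, seed = 9, noise = quiet_noise())
  mk <- s$trials$TM$markers
  R10 <- cardan_rotation(c(10, 0, 0))
  mk_rot <- mk
  for (m in aquagait:::MODEL_MARKERS) {
    cols <- paste0(m, c("_x", "_y", "_z"))
    mk_rot[cols] <- as.data.frame(as.matrix(mk[cols]) %*% t(R10))
  }
  f1 <- build_segment_frames(mk)
  f2 <- build_segment_frames(mk_rot)
  expect_equal(f2$pelvis[, , 7], R10 %*% f1$pelvis[, , 7], tolerance = 1e-9)
})

test_that("all five angles are invariant under translation and heading rotation", {
  s <- generate_session(duration = 5, seed = 9, noise = quiet_noise())
  tr <- s$trials$TM
  a0 <- compute_angles(tr, s$static)
  # translate and rotate all markers about the vertical axis
  Rz <- cardan_rotation(c(0, 0, 35))
  tr2 <- tr
  for (m in aquagait:::MODEL_MARKERS) {
    cols <- paste0(m, c("_x", "_y", "_z"))
    tr2$markers[cols] <- sweep(as.matrix(tr$markers[cols]) %*% t(Rz), 2,
                               c(500, -300, 90), `+`)
  }
  a1 <- compute_angles(tr2, s$static)
  for (a in aquagait:::ANGLE_NAMES)
    expect_equal(a1[[a]], a0[[a]], tolerance = 1e-6)
})

test_that("swapping the tuber coxae negates yaw and the pitch component, keeping pitch magnitude", {
  s <- generate_session(duration = 5, seed = 9, noise = quiet_noise())
  tr <- s$trials$TM
  a0 <- compute_angles(tr, s$static)
  tr2 <- tr
  l_cols <- paste0("LTC", c("_x", "_y", "_z"))
  r_cols <- paste0("RTC", c("_x", "_y", "_z"))
  tmp <- tr2$markers[l_cols]
  tr2$markers[l_cols] <- setNames(tr2$markers[r_cols], l_cols)
  tr2$markers[r_cols] <- setNames(tmp, r_cols)
  a1 <- compute_angles(tr2, s$static)
  expect_equal(a1$pelvis_roll, -a0$pelvis_roll, tolerance = 1e-9)
  expect_equal(a1$pelvis_yaw, -a0$pelvis_yaw, tolerance = 1e-9)
  expect_equal(abs(a1$pelvis_pitch), abs(a0$pelvis_pitch), tolerance = 1e-9)
})

test_that("a trial frozen at the static pose yields zero normalised sagittal angles", {
  s <- generate_session(duration = 5, seed = 9, noise = quiet_noise())
  tr <- s$trials$TM
  n <- nrow(tr$markers)
  static_row <- s$static$markers
  for (cc in names(static_row))
    tr$markers[[cc]] <- rep(static_row[[cc]], n)
  tr$markers$time <- seq(0, by = 1 / 200, length.out = n)
  tr$markers <- aquagait:::add_gap_flags(tr$markers)
  aw <- compute_angles(tr, s$static)
  expect_lt(max(abs(aw$thoraco_flex_ext)), 1e-9)
  expect_lt(max(abs(aw$pelvis_pitch)), 1e-9)
  expect_lt(max(abs(aw$thoraco_lat_bend)), 1e-9)
})

test_that("angles recover the prescribed waveforms (noise-free and 1 mm noise)", {
  for (case in list(list(sd = 0, tol = 0.5), list(sd = 1, tol = 2))) {
    s <- generate_session(duration = 30, seed = 13,
                          noise = noise_spec(marker_sd = case$sd))
    tr <- s$trials$WT80
    aw <- compute_angles(tr, s$static)
    phi <- aquagait:::stride_phase(tr$markers$time,
                                   s$truth$impact_times$WT80) %% 1
    mid <- tr$markers$time > 2 & tr$markers$time < 28
    for (a in aquagait:::ANGLE_NAMES) {
      truth <- truth_angle_at(s, "WT80", a, phi)
      rmse <- sqrt(mean((aw[[a]][mid] - truth[mid])^2))
      expect_lt(rmse, case$tol)
    }
  }
})

test_that("filtering leaves the mean of a stationary angle series untouched", {
  s <- generate_session(duration = 30, seed = 13, noise = quiet_noise())
  tr <- s$trials$TM
  aw_raw <- aquagait:::raw_angles(tr$markers)
  aw <- compute_angles(tr, s$static)
  static_flex <- attr(aw, "static_angles")$thoraco_flex_ext
  expect_lt(abs(mean(aw$thoraco_flex_ext) -
                  (mean(aw_raw$thoraco_flex_ext) - static_flex)), 1e-6)
})

test_that("a missing static trial skips normalisation with a warning", {
  s <- generate_session(duration = 5, seed = 9, noise = quiet_noise())
  expect_warning(aw <- compute_angles(s$trials$TM, static = NULL),
                 "static")
  expect_false(attr(aw, "static_normalised"))
})
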