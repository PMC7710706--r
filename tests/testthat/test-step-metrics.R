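test_that("step geometry matches hand-computed extreme-position cases", {
  # AEP (3,4), PEP (0,0): 3-4-5 triangle
  g <- step_geometry(rbind(c(0, 0), c(3, 4), c(1, 1)))
  expect_equal(g$step_size, 5)
  # AEP (2,0), PEP (0,0), DEP (1,1): amplitude 1
  g2 <- step_geometry(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(g2$swing_stroke_amplitude, 1)
  # DEP beyond the segment x-extent: distance to the nearest endpoint
  g3 <- step_geometry(rbind(c(0, 0), c(2, 0), c(3, 1)))
  expect_equal(g3$aep, c(3, 1), ignore_attr = TRUE)
  expect_equal(g3$swing_stroke_amplitude,
               brute_seg_dist(c(3, 1), g3$aep, g3$pep), tolerance = 1e-6)
  # fewer than 3 distinct points: amplitude undefined and flagged
  expect_warning(g4 <- step_geometry(rbind(c(0, 0), c(1, 0), c(1, 0))),
                 "undefined")
  expect_true(g4$degenerate && is.na(g4$swing_stroke_amplitude))
})

test_that("amplitude equals the dense-sampling oracle and survives time reversal", {
  set.seed(31)
  for (i in 1:40) {
    traj <- cbind(runif(30, -2, 2), runif(30, -1, 1))
    g <- step_geometry(traj)
    expect_equal(g$swing_stroke_amplitude,
                 brute_seg_dist(g$dep, g$aep, g$pep), tolerance = 1e-6)
    rev_g <- step_geometry(traj[nrow(traj):1, ])
    expect_equal(rev_g$step_size, g$step_size)
    expect_equal(rev_g$swing_stroke_amplitude, g$swing_stroke_amplitude)
  }
})

test_that("zero-noise gait reproduces the programmed step geometry exactly", {
  ds <- default_gait()
  tip <- ds$pose$coords[, "RM_tarsal_tip", ]
  g <- step_geometry(tip)
  expect_equal(g$step_size, ds$params$aep_x - ds$params$pep_x)
  expect_equal(g$swing_stroke_amplitude, ds$params$swing_height,
               tolerance = 1e-3)
})

test_that("joint angle range is max minus min, ignoring missing frames", {
  expect_equal(joint_angle_range(c(100, NA, 60, 150)), 90)
  expect_true(is.na(joint_angle_range(c(NA_real_, NA_real_))))
})

test_that("max flexion stops at the first re-extension", {
  fps <- 100
  # monotone decrease 120 -> 60 within the window
  tr <- c(rep(120, 50), seq(120, 60, length.out = 100), rep(60, 50))
  expect_equal(max_flexion(tr, fps, onset_s = 0.5), 60)
  # dip to 80, re-extension > 5 deg, deeper dip to 50: pre-re-extension minimum
  tr2 <- c(rep(120, 10), seq(120, 80, length.out = 30), seq(80, 100, length.out = 20),
           seq(100, 50, length.out = 40), rep(50, 20))
  expect_equal(max_flexion(tr2, fps, onset_s = 0.1), 80)
  # flat trace: the baseline angle
  expect_equal(max_flexion(rep(95, 200), fps, onset_s = 0.2), 95)
  expect_error(max_flexion(rep(95, 50), fps, onset_s = 0.2), "cover")
})

test_that("minimum pre-peak angle follows the stance rule", {
  v <- c(90, 70, 45, 80, 120, 100)
  expect_equal(min_step_angle(v, peak_pos = 5), 45)
  expect_equal(min_step_angle(seq(60, 160, by = 20), peak_pos = 6), 60)
  expect_warning(m <- min_step_angle(v, peak_pos = 1), "undefined")
  expect_true(is.na(m))
})

test_that("min pre-peak angle on simulated gait matches the stance minimum", {
  ds <- default_gait(f_hz = 2)
  pk <- detect_swing_peaks(ds$pose, "LH")
  ang <- ds$true_angles$LH[, "femur_tibia"]
  ens <- segment_steps(cbind(femur_tibia = ang), pk,
                       spec = step_window_preset("fig_short"))
  s <- ens$steps[[3]]
  got <- min_step_angle(s$traces[, "femur_tibia"],
                        which(s$frames == s$peak_frame))
  # oracle: minimum over the stance+early-swing frames preceding this peak
  pre <- ang[(s$frames[1]):(s$peak_frame - 1)]
  expect_equal(got, min(pre))
})

test_that("flexion slope recovers linear declines by least squares", {
  fps <- 200
  tt <- seq(0, 1.495, by = 1 / fps)
  expect_equal(flexion_slope(140 - 100 * tt, fps), -100, tolerance = 1e-9)
  expect_equal(flexion_slope(rep(90, 300), fps), 0)
  # rise then linear decline: fit starts at the maximum
  tr <- c(seq(90, 139, length.out = 40), 140 - 100 * (0:259) / fps)
  expect_equal(flexion_slope(tr, fps), -100, tolerance = 1e-9)
  # noisy line: slope within +-3 deg/s of truth at 260 fit points
  set.seed(8)
  est <- replicate(20, {
    y <- c(150, 140 - 100 * seq(0, 1.3, length.out = 260) + rnorm(260, 0, 2))
    flexion_slope(y, fps)
  })
  expect_true(all(abs(est + 100) < 3))
  expect_error(flexion_slope(c(NA, NA, 1), fps), "fewer than 2")
})
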