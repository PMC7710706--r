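test_that("window presets carry the documented constants", {
  long <- step_window_preset("fig_long")
  expect_identical(c(long$window, long$placement, long$margin), c(300L, 40L, 8L))
  short <- step_window_preset("fig_short")
  expect_identical(c(short$window, short$placement, short$margin), c(100L, 49L, 8L))
  expect_error(step_window_spec(100, 100, 8), "placement")
})

test_that("an isolated peak yields the full nominal window", {
  tr <- cbind(tip_y = rnorm(2000))
  # 0-based frame 1000 is 1-based index 1001
  ens <- segment_steps(tr, peaks = 1001L, spec = step_window_spec(300, 40, 8),
                       fps = 200)
  s <- ens$steps[[1]]
  expect_identical(range(s$frames), c(961L, 1260L))  # 0-based 960..1259
  expect_identical(length(s$frames), 300L)
  expect_identical(s$pos[s$frames == 1001L], 41L)    # peak at window index 40 (0-based)
  expect_false(s$truncated_pre || s$truncated_post)
})

test_that("a following peak truncates the step at the margin", {
  tr <- cbind(tip_y = rnorm(2000))
  ens <- segment_steps(tr, peaks = c(1001L, 1101L),
                       spec = step_window_spec(300, 40, 8), fps = 200)
  s1 <- ens$steps[[1]]
  # post-peak portion is 92 frames: the step ends 8 frames before the next peak
  expect_identical(sum(s1$frames >= 1001L), 92L)
  expect_true(s1$truncated_post)
  # a close preceding peak truncates the pre-peak side symmetrically
  ens_close <- segment_steps(tr, peaks = c(1001L, 1031L),
                             spec = step_window_spec(300, 40, 8), fps = 200)
  s2 <- ens_close$steps[[2]]
  expect_identical(s2$frames[1], 1001L + 9L)
  expect_true(s2$truncated_pre)
})

test_that("steps are clipped at trace and analysis-window boundaries", {
  tr <- cbind(tip_y = rnorm(400))
  ens <- segment_steps(tr, peaks = 11L, spec = step_window_spec(300, 40, 8),
                       fps = 200)
  s <- ens$steps[[1]]
  expect_identical(s$frames[1], 1L)
  expect_identical(s$pos[s$frames == 11L], 41L)
  expect_true(s$truncated_pre)
  # peaks outside the analysis window are dropped and counted
  ens2 <- segment_steps(tr, peaks = c(50L, 350L), spec = step_window_spec(100, 49, 8),
                        fps = 200, analysis_window = c(1L, 300L))
  expect_identical(length(ens2$steps), 1L)
  expect_identical(ens2$n_dropped, 1L)
})

test_that("post-peak regions of consecutive steps never overlap", {
  set.seed(2)
  peaks <- sort(sample(100:1900, 25))
  peaks <- peaks[c(TRUE, diff(peaks) > 20)]
  tr <- cbind(tip_y = rnorm(2000))
  ens <- segment_steps(tr, peaks, spec = step_window_spec(300, 40, 8), fps = 200)
  claimed <- integer(0)
  for (s in ens$steps) {
    post <- s$frames[s$frames >= s$peak_frame]
    expect_length(intersect(claimed, post), 0)
    claimed <- c(claimed, post)
  }
})

test_that("averaging handles identical and truncated steps correctly", {
  spec <- step_window_spec(100, 49, 8)
  base <- sin(seq(0, 2 * pi, length.out = 100))
  tr <- cbind(tip_y = c(base, base, base, rnorm(100)))
  # identical isolated steps: average equals any member
  ens <- segment_steps(tr, peaks = c(50L, 150L, 250L), spec = spec, fps = 200)
  av <- average_steps(ens, height_col = NULL)
  expect_equal(av$mean[, "tip_y"], base, ignore_attr = TRUE)
  # one clipped step: positions it misses average to the complete step alone
  ens2 <- segment_steps(tr, peaks = c(30L, 300L), spec = spec, fps = 200)
  av2 <- average_steps(ens2, height_col = NULL)
  expect_true(ens2$steps[[1]]$truncated_pre)
  expect_equal(av2$mean[1:20, "tip_y"], tr[251:270, "tip_y"], ignore_attr = TRUE)
  expect_true(all(av2$n[1:20] == 1) && all(av2$n[21:100] == 2))
  expect_error(average_steps(segment_steps(tr, integer(0), spec, fps = 200)),
               "empty")
})

test_that("inferred swing interval overlaps the true swing bout (Jaccard >= 0.8)", {
  ds <- default_gait(f_hz = 2, duration_s = 5)
  leg <- "LF"
  pk <- detect_swing_peaks(ds$pose, leg)
  tip <- ds$pose$coords[, paste0(leg, "_tarsal_tip"), ]
  ens <- segment_steps(cbind(tip_x = tip[, 1], tip_y = tip[, 2]), pk,
                       spec = step_window_preset("fig_short"))
  av <- average_steps(ens)
  expect_false(is.null(av$swing_interval))
  # true swing positions within the window, relative to an interior peak
  p <- pk$peaks[3]
  win_frames <- (p - 49):(p + 50)
  true_sw <- which(ds$true_swing_mask$mask[leg, win_frames])
  inferred <- av$swing_interval["start"]:av$swing_interval["end"]
  jac <- length(intersect(true_sw, inferred)) / length(union(true_sw, inferred))
  expect_gte(jac, 0.8)
})
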