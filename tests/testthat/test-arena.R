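straight_track <- function(speed_mm_s, heading = 0, move_angle = heading,
                           duration_s = 600, fps = 30, id = "t") {
  n <- duration_s * fps
  tt <- (0:(n - 1)) / fps
  centroid_track(x = speed_mm_s * tt * cos(move_angle),
                 y = speed_mm_s * tt * sin(move_angle),
                 heading = rep(heading, n), fps = fps, fly_id = id)
}

test_that("heading-projected speed resolves forward, backward, and sideslip", {
  expect_equal(heading_speed(straight_track(2, heading = 0.6, duration_s = 1)),
               rep(2, 29), tolerance = 1e-12)
  expect_equal(heading_speed(straight_track(2, heading = 0.6,
                                            move_angle = 0.6 + pi, duration_s = 1)),
               rep(-2, 29), tolerance = 1e-12)
  expect_equal(heading_speed(straight_track(2, heading = 0.6,
                                            move_angle = 0.6 + pi / 2, duration_s = 1)),
               rep(0, 29), tolerance = 1e-12)
  expect_error(heading_speed(centroid_track(1, 1, 0)), "2 frames")
})

test_that("backward distance integrates thresholded episode frames only", {
  sched <- episode_schedule()
  # constant backward 2 mm/s through all nine 5-s episodes -> 90 mm
  bw <- straight_track(2, heading = 0, move_angle = pi)
  expect_equal(backward_distance(bw, sched), 90, tolerance = 1e-9)
  # below the 1.5 mm/s threshold -> 0 mm
  slow <- straight_track(1, heading = 0, move_angle = pi)
  expect_equal(backward_distance(slow, sched), 0)
  # forward walkers contribute nothing
  expect_equal(backward_distance(straight_track(3), sched), 0)
  expect_error(backward_distance(straight_track(2, duration_s = 100), sched),
               "shorter")
})

test_that("forward distance is the signed pre-stimulus integral", {
  expect_equal(forward_distance(straight_track(3, duration_s = 60)), 135,
               tolerance = 1e-9)
  still <- centroid_track(rep(0, 1800), rep(0, 1800), rep(1, 1800), fps = 30)
  expect_equal(forward_distance(still), 0)
  # alternating +-1 mm/s cancels
  n <- 1800
  v <- rep(c(1, -1), n / 2)
  x <- cumsum(c(0, v[-n] / 30))
  alt <- centroid_track(x, rep(0, n), rep(0, n), fps = 30)
  expect_equal(forward_distance(alt), 0, tolerance = 1e-9)
})

test_that("simulated arena distances are recovered within one frame displacement", {
  params <- arena_sim_params(n_flies = 6, responder_fraction = 0.5,
                             backward_speed = 4, seed = 17)
  sim <- simulate_arena(params)
  one_frame <- params$backward_speed / params$fps
  for (i in seq_along(sim$tracks)) {
    got <- backward_distance(sim$tracks[[i]], params$schedule)
    expect_lt(abs(got - sim$truth$backward_mm[i]), one_frame + 1e-9)
  }
  expect_identical(sum(sim$truth$responder), 3L)
  # responder fraction 0: all true distances zero
  sim0 <- simulate_arena(arena_sim_params(n_flies = 3, responder_fraction = 0,
                                          seed = 2))
  expect_true(all(sim0$truth$backward_mm == 0))
  expect_true(all(vapply(sim0$tracks, backward_distance, numeric(1),
                         schedule = episode_schedule()) == 0))
})

test_that("backward distance is non-increasing in the threshold", {
  sim <- simulate_arena(arena_sim_params(n_flies = 1, backward_speed = 2.5,
                                         heading_noise_sd = 0.3, seed = 23))
  d <- vapply(c(0, 0.5, 1.5, 2, 2.4, 2.6, 5),
              function(th) backward_distance(sim$tracks[[1]],
                                             episode_schedule(), th),
              numeric(1))
  expect_true(all(diff(d) <= 1e-12))
  expect_true(all(d >= 0))
  expect_equal(d[length(d)], 0)
})

test_that("cohort summary aggregates per-fly distances", {
  t1 <- straight_track(2, heading = 0, move_angle = pi, id = "a")
  t2 <- straight_track(4, heading = 0, move_angle = pi, id = "b")
  cs <- cohort_summary(list(t1, t2))
  expect_equal(sort(cs$per_fly$backward_mm), c(90, 180), tolerance = 1e-9)
  expect_equal(cs$cohort$mean[cs$cohort$metric == "backward_mm"], 135,
               tolerance = 1e-9)
  # single fly: mean is its own value, s.e.m. undefined
  cs1 <- cohort_summary(list(t1))
  expect_equal(cs1$cohort$mean[2], 90, tolerance = 1e-9)
  expect_true(is.na(cs1$cohort$sem[2]))
  # a half-responder cohort averages to half the responder truth
  sim <- simulate_arena(arena_sim_params(n_flies = 4, responder_fraction = 0.5,
                                         seed = 3))
  cs2 <- cohort_summary(sim$tracks, sim$params$schedule)
  expect_equal(cs2$cohort$mean[cs2$cohort$metric == "backward_mm"],
               0.5 * max(sim$truth$backward_mm), tolerance = 0.2)
})

test_that("arena CSV IO round-trips tracks", {
  sim <- simulate_arena(arena_sim_params(n_flies = 2, duration_s = 550, seed = 6))
  f <- withr::local_tempfile(fileext = ".csv")
  write_arena_csv(sim$tracks, f)
  back <- read_arena_csv(f, fps = 30)
  expect_setequal(names(back), c("fly01", "fly02"))
  for (id in names(back)) {
    orig <- sim$tracks[[which(vapply(sim$tracks, `[[`, "", "fly_id") == id)]]
    expect_equal(back[[id]]$x, orig$x, tolerance = 1e-9)
    expect_equal(back[[id]]$heading, orig$heading, tolerance = 1e-9)
  }
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_arena_csv(bad), "columns")
})
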