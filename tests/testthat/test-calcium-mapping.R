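test_that("maxlag 5 yields 11 covariance values per voxel", {
  sim <- simulate_calcium(small_scene(noise_sd = 1))
  fld <- voxel_crosscov(concat_sessions(sim$recording), sim$truth$kernel)
  expect_identical(dim(fld$cov)[1], 11L)
  expect_identical(fld$lags, -5:5)
})

test_that("cross-covariance matches a brute-force double loop", {
  set.seed(19)
  p <- stimulus_protocol("20s", session_volumes = 30)
  k <- rnorm(30)
  for (rep in 1:10) {
    hy <- array(rnorm(60 * 1 * 2 * 5), c(60, 1, 2, 5))  # 2 tiled sessions
    maxlag <- sample(0:5, 1)
    fld <- voxel_crosscov(hy, k, maxlag = maxlag)
    v <- c(sample(2, 1), sample(5, 1))
    got <- fld$cov[, 1, v[1], v[2]]
    expect_equal(got, brute_xcov(hy[, 1, v[1], v[2]], rep(k, 2), maxlag),
                 tolerance = 1e-10)
  }
  # constant voxel series -> all values zero
  hy0 <- array(5, c(60, 1, 2, 2))
  expect_true(all(voxel_crosscov(hy0, k)$cov == 0))
  expect_error(voxel_crosscov(array(0, c(50, 1, 2, 2)), k), "multiple")
})

test_that("cross-covariance is linear in the voxel series", {
  set.seed(23)
  k <- rnorm(20)
  hy <- array(rnorm(40 * 8), c(40, 2, 2, 2))
  f1 <- voxel_crosscov(hy, k, maxlag = 3)
  f2 <- voxel_crosscov(hy * 4.5, k, maxlag = 3)
  expect_equal(f2$cov, 4.5 * f1$cov, tolerance = 1e-10)
  # biased normalization rescales uniformly by 1/T
  fb <- voxel_crosscov(hy, k, maxlag = 3, normalization = "biased")
  expect_equal(fb$cov, f1$cov / 40, tolerance = 1e-12)
})

test_that("response maps floor/ceiling the lag extrema with the right signs", {
  set.seed(29)
  k <- rnorm(20)
  hy <- array(rnorm(40 * 8), c(40, 2, 2, 2))
  fld <- voxel_crosscov(hy, k, maxlag = 5)
  maps <- response_maps(fld)
  expect_true(all(maps$activated >= 0) && all(maps$inhibited <= 0))
  for (v in list(c(1, 1, 1), c(2, 2, 2), c(1, 2, 1))) {
    vec <- fld$cov[, v[1], v[2], v[3]]
    expect_equal(maps$activated[v[1], v[2], v[3]], max(0, max(vec)))
    expect_equal(maps$inhibited[v[1], v[2], v[3]], min(0, min(vec)))
  }
  # negating the series swaps the maps
  maps_neg <- response_maps(voxel_crosscov(-hy, k, maxlag = 5))
  expect_equal(maps_neg$activated, -maps$inhibited, tolerance = 1e-10)
  expect_equal(maps_neg$inhibited, -maps$activated, tolerance = 1e-10)
})

test_that("a voxel equal to the tiled kernel peaks at lag zero with sum of squares", {
  k <- make_gcamp_kernel(stimulus_protocol("20s"))$trace
  tiled <- rep(k, 3)
  hy <- array(rnorm(180 * 4), c(180, 1, 2, 2))
  hy[, 1, 1, 1] <- tiled
  fld <- voxel_crosscov(hy, k, maxlag = 5)
  vec <- fld$cov[, 1, 1, 1]
  expect_equal(which.max(vec), 6L)  # lag 0
  expect_equal(max(vec), sum((tiled - mean(tiled))^2), tolerance = 1e-10)
})

test_that("lagged synthetic cells are detected at their true lag", {
  for (d in c(-4L, 0L, 3L)) {
    sim <- simulate_calcium(small_scene(noise_sd = 0, amplitude = 1, lag = d))
    fld <- voxel_crosscov(concat_sessions(sim$recording), sim$truth$kernel)
    lag_map <- peak_lag_map(fld)
    expect_true(all(lag_map[sim$truth$labels == 1L] == d))
  }
  # a lag beyond maxlag scores lower than the matched-lag case
  sim_in <- simulate_calcium(small_scene(noise_sd = 0, amplitude = 1, lag = 0))
  sim_out <- simulate_calcium(small_scene(noise_sd = 0, amplitude = 1, lag = 9))
  act_in <- response_maps(voxel_crosscov(concat_sessions(sim_in$recording),
                                         sim_in$truth$kernel))$activated
  act_out <- response_maps(voxel_crosscov(concat_sessions(sim_out$recording),
                                          sim_out$truth$kernel))$activated
  cellv <- sim_in$truth$labels == 1L
  expect_lt(max(act_out[cellv]), min(act_in[cellv]))
})

test_that("activated and inhibited cells are recovered with precision/recall >= 0.9", {
  dims <- c(8, 32, 64)
  cells <- list(
    list(mask = cuboid_mask(c(3, 8, 12), c(1, 2, 2), dims), amplitude = 0.6,
         lag_volumes = 0),
    list(mask = cuboid_mask(c(6, 22, 40), c(1, 2, 2), dims), amplitude = 0.5,
         lag_volumes = 3),
    list(mask = cuboid_mask(c(4, 15, 55), c(1, 2, 2), dims), amplitude = -0.5,
         lag_volumes = 0))
  scene <- calcium_scene(dims, cells, baseline = 100, noise_sd = 10,
                         protocol = stimulus_protocol("20s"),
                         n_sessions = 10, seed = 41)
  sim <- simulate_calcium(scene)
  fld <- voxel_crosscov(concat_sessions(sim$recording), sim$truth$kernel)
  maps <- response_maps(fld)
  truth_pos <- sim$truth$labels %in% which(sim$truth$amplitudes > 0)
  truth_neg <- sim$truth$labels %in% which(sim$truth$amplitudes < 0)
  hit_pos <- threshold_map(maps$activated, 3)
  hit_neg <- threshold_map(maps$inhibited, 3, side = "inhibited")
  prec <- sum(hit_pos & truth_pos) / sum(hit_pos)
  rec <- sum(hit_pos & truth_pos) / sum(truth_pos)
  expect_gte(prec, 0.9)
  expect_gte(rec, 0.9)
  prec_n <- sum(hit_neg & truth_neg) / sum(hit_neg)
  rec_n <- sum(hit_neg & truth_neg) / sum(truth_neg)
  expect_gte(prec_n, 0.9)
  expect_gte(rec_n, 0.9)
})

test_that("background intensity is conserved around the baseline", {
  sim <- simulate_calcium(small_scene(noise_sd = 5, n_sessions = 1, seed = 13))
  s <- sim$recording$sessions[[1]]
  dim(s) <- c(dim(s)[1], length(sim$truth$labels))
  bg <- s[, as.vector(sim$truth$labels) == 0L]
  n <- length(bg)
  expect_lt(abs(mean(bg) - 100), 3 * 5 / sqrt(n))
})
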