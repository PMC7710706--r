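# shared fixtures, all generated in code

default_gait <- function(f_hz = 2, duty = 0.5, noise = 0, seed = 7,
                         duration_s = 5, fps = 200, direction = "forward") {
  simulate_gait(gait_params(step_frequency_hz = f_hz, duty_factor = duty,
                            landmark_noise_sd = noise, seed = seed,
                            direction = direction),
                duration_s = duration_s, fps = fps)
}

small_scene <- function(noise_sd = 0, n_sessions = 3, seed = 11,
                        amplitude = 1, lag = 0, preset = "20s",
                        dims = c(4, 10, 12)) {
  calcium_scene(
    dims = dims,
    cells = list(list(mask = cuboid_mask(c(2, 4, 5), c(0, 1, 1), dims),
                      amplitude = amplitude, lag_volumes = lag)),
    baseline = 100, noise_sd = noise_sd,
    protocol = stimulus_protocol(preset),
    n_sessions = n_sessions, seed = seed)
}

# brute-force lagged cross-covariance: double loop over tau and t
brute_xcov <- function(x, k, maxlag) {
  xc <- x - mean(x)
  kc <- k - mean(k)
  n <- length(x)
  vapply((-maxlag):maxlag, function(tau) {
    s <- 0
    for (t in seq_len(n)) {
      u <- t + tau
      if (u >= 1 && u <= n) s <- s + xc[u] * kc[t]
    }
    s
  }, numeric(1))
}

# brute-force point-to-segment distance by dense sampling
brute_seg_dist <- function(p, a, b, n = 1e4) {
  tt <- seq(0, 1, length.out = n)
  min(sqrt((p[1] - (a[1] + tt * (b[1] - a[1])))^2 +
             (p[2] - (a[2] + tt * (b[2] - a[2])))^2))
}
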