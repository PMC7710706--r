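#' Synthetic calcium scene parameters
#'
#' Describes a volumetric scene of responsive cells on a constant
#' baseline: each cell is a disjoint voxel mask with a signed response
#' amplitude `amplitude` (dF/F units; negative = inhibited), a response
#' lag in volumes, and the common baseline intensity. Noise is additive
#' Gaussian per voxel and volume.
#'
#' @param dims integer length-3 grid size (Z, Y, X).
#' @param cells list of cells; each cell is a list with `mask` (n x 3
#'   (z,y,x) index matrix or logical array), `amplitude`, and
#'   `lag_volumes`.
#' @param baseline baseline intensity F0 (> 0, default 100).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param protocol a [stimulus_protocol()].
#' @param n_sessions sessions to simulate (default 10).
#' @param seed master seed; each session draws from its own derived
#'   stream.
#' @return an object of class `calcium_scene_params`.
#' @export
calcium_scene <- function(dims, cells, baseline = 100, noise_sd = 1,
                          protocol = stimulus_protocol("20s"),
                          n_sessions = 10L, seed = 1L) {
  stopifnot(length(dims) == 3, baseline > 0, noise_sd >= 0,
            inherits(protocol, "stimulus_protocol"))
  dims <- as.integer(dims)
  seen <- array(FALSE, dims)
  cells <- lapply(cells, function(cl) {
    cl$mask <- roi_voxels(cl$mask, dims)
    cl
  })
  for (cl in cells) {
    lin <- (cl$mask[, 3] - 1) * dims[1] * dims[2] +
      (cl$mask[, 2] - 1) * dims[1] + cl$mask[, 1]
    if (any(seen[lin])) stop("cell masks must be disjoint")
    seen[lin] <- TRUE
  }
  structure(list(dims = dims, cells = cells, baseline = baseline,
                 noise_sd = noise_sd, protocol = protocol,
                 n_sessions = as.integer(n_sessions), seed = as.integer(seed)),
            class = "calcium_scene_params")
}

#' Cuboid cell mask helper
#'
#' @param center integer length-3 (z, y, x) center voxel.
#' @param half_size integer length-3 half-extents; the mask spans
#'   `center - half_size : center + half_size` on each axis.
#' @param dims grid size for bounds clipping.
#' @return an n x 3 (z, y, x) index matrix.
#' @export
cuboid_mask <- function(center, half_size, dims) {
  rng <- lapply(1:3, function(i)
    max(1, center[i] - half_size[i]):min(dims[i], center[i] + half_size[i]))
  as.matrix(expand.grid(z = rng[[1]], y = rng[[2]], x = rng[[3]]))
}

# kernel shifted right by lag volumes (zero-padded)
shift_kernel <- function(k, lag) {
  n <- length(k)
  out <- numeric(n)
  src <- seq_len(n) - lag
  ok <- src >= 1 & src <= n
  out[ok] <- k[src[ok]]
  out
}

#' Simulate a volumetric calcium recording with known ground truth
#'
#' Every session shares the same deterministic signal: background voxels
#' sit at the baseline `F0`; a voxel of cell `k` follows
#' `F0 * (1 + amplitude_k * kernel(t - lag_k))` where the kernel is the
#' [make_gcamp_kernel()] response to the scene's stimulus protocol.
#' Independent Gaussian noise is added per session from per-session
#' random streams derived from the master seed.
#'
#' @param scene a [calcium_scene()].
#' @param tau_rise_s,tau_decay_s kernel time constants passed to
#'   [make_gcamp_kernel()].
#' @return list of class `synthetic_calcium_dataset`: `recording` (a
#'   [sample_recording()]), `truth` (label array `Z x Y x X` with 0 =
#'   background and the cell index elsewhere, per-cell amplitudes and
#'   lags, the noise-free kernel), `scene`.
#' @export
simulate_calcium <- function(scene, tau_rise_s = 0.2, tau_decay_s = 1.5) {
  stopifnot(inherits(scene, "calcium_scene_params"))
  kern <- make_gcamp_kernel(scene$protocol, tau_rise_s, tau_decay_s)
  nt <- scene$protocol$session_volumes
  d <- scene$dims
  V <- prod(d)

  clean <- matrix(scene$baseline, nt, V)
  labels <- array(0L, d)
  for (ci in seq_along(scene$cells)) {
    cl <- scene$cells[[ci]]
    if (abs(cl$lag_volumes) > nt)
      stop("cell lag exceeds the session length")
    lin <- (cl$mask[, 3] - 1) * d[1] * d[2] + (cl$mask[, 2] - 1) * d[1] + cl$mask[, 1]
    labels[lin] <- ci
    resp <- scene$baseline *
      (1 + cl$amplitude * shift_kernel(kern$trace, cl$lag_volumes))
    clean[, lin] <- resp
  }

  sessions <- vector("list", scene$n_sessions)
  for (s in seq_len(scene$n_sessions)) {
    m <- clean
    if (scene$noise_sd > 0) {
      set.seed(derive_seed(scene$seed, s, stream = 1L))
      m <- m + matrix(stats::rnorm(nt * V, 0, scene$noise_sd), nt, V)
    }
    dim(m) <- c(nt, d)
    sessions[[s]] <- m
  }
  rec <- sample_recording(sessions, scene$protocol)
  structure(list(recording = rec,
                 truth = list(labels = labels,
                              amplitudes = vapply(scene$cells, `[[`, numeric(1), "amplitude"),
                              lags = vapply(scene$cells, `[[`, numeric(1), "lag_volumes"),
                              kernel = kern),
                 scene = scene),
            class = "synthetic_calcium_dataset")
}
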