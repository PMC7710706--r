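#' Per-voxel lagged cross-covariance with a response kernel
#'
#' For every voxel time series `x` of the hyperstack and the
#' session-length kernel `k` tiled across sessions, computes the
#' unnormalized demeaned lagged products
#' `c(tau) = sum_t (x[t + tau] - mean(x)) * (k[t] - mean(k))`
#' for `tau = -maxlag ... +maxlag`, with zero contribution outside the
#' overlap. Positive `tau` means the voxel series lags the kernel, so a
#' delayed (e.g. polysynaptically driven) response peaks at its delay in
#' volumes. With the default `maxlag = 5` each voxel receives 11 values.
#'
#' @param hyperstack `T x Z x Y x X` array (see [concat_sessions()]).
#' @param kernel a `response_kernel` or numeric session-length trace;
#'   tiled to the hyperstack length (T must be a multiple of the kernel
#'   length).
#' @param maxlag maximum lag in volumes (default 5).
#' @param normalization `"none"` (raw sums, default) or `"biased"`
#'   (divide by T; rescales all values identically).
#' @return an object of class `voxel_cov_field`: `cov` (array
#'   `(2*maxlag+1) x Z x Y x X`), `lags`, `maxlag`, `normalization`.
#' @export
voxel_crosscov <- function(hyperstack, kernel, maxlag = 5,
                           normalization = c("none", "biased")) {
  normalization <- match.arg(normalization)
  k <- if (inherits(kernel, "response_kernel")) kernel$trace else as.numeric(kernel)
  d <- dim(hyperstack)
  nt <- d[1]
  if (nt %% length(k) != 0)
    stop("hyperstack length is not a multiple of the kernel length")
  k <- rep(k, nt / length(k))
  kc <- k - mean(k)
  V <- prod(d[2:4])
  X <- hyperstack
  dim(X) <- c(nt, V)
  X <- sweep(X, 2, colMeans(X))
  lags <- (-maxlag):maxlag
  cv <- matrix(0, length(lags), V)
  for (i in seq_along(lags)) {
    tau <- lags[i]
    tt <- seq_len(nt)            # kernel index t; voxel index t + tau
    tt <- tt[tt + tau >= 1 & tt + tau <= nt]
    cv[i, ] <- crossprod(X[tt + tau, , drop = FALSE], kc[tt])
  }
  if (normalization == "biased") cv <- cv / nt
  dim(cv) <- c(length(lags), d[2], d[3], d[4])
  structure(list(cov = cv, lags = lags, maxlag = maxlag,
                 normalization = normalization),
            class = "voxel_cov_field")
}

#' Activated and inhibited response maps from a covariance field
#'
#' Per voxel, the activated map keeps the maximal positive lagged
#' cross-covariance (0 if all lags are negative) and the inhibited map
#' the minimal negative one (0 if all lags are positive).
#'
#' @param field a [voxel_crosscov()] result.
#' @return an object of class `response_maps`: `activated` (>= 0) and
#'   `inhibited` (<= 0), each a `Z x Y x X` array.
#' @export
response_maps <- function(field) {
  stopifnot(inherits(field, "voxel_cov_field"))
  d <- dim(field$cov)
  cv <- field$cov
  dim(cv) <- c(d[1], prod(d[2:4]))
  act <- pmax(0, apply(cv, 2, max))
  inh <- pmin(0, apply(cv, 2, min))
  dim(act) <- d[2:4]
  dim(inh) <- d[2:4]
  structure(list(activated = act, inhibited = inh), class = "response_maps")
}

#' Best-matching lag per voxel
#'
#' The lag (in volumes) at which each voxel's cross-covariance is
#' maximal; useful for reading off response delays of mapped cells.
#'
#' @param field a [voxel_crosscov()] result.
#' @return integer `Z x Y x X` array of lags.
#' @export
peak_lag_map <- function(field) {
  stopifnot(inherits(field, "voxel_cov_field"))
  d <- dim(field$cov)
  cv <- field$cov
  dim(cv) <- c(d[1], prod(d[2:4]))
  lag <- field$lags[apply(cv, 2, which.max)]
  dim(lag) <- d[2:4]
  lag
}

#' Threshold a response map against its background spread
#'
#' Classifies voxels as responsive when the map magnitude exceeds
#' `sd_factor` times a robust estimate (median absolute deviation about
#' zero) of the background spread of the map's nonzero values. Use on
#' the activated map for positive responders and on the inhibited map
#' (`side = "inhibited"`) for negative ones.
#'
#' @param map one map out of [response_maps()] (`Z x Y x X`).
#' @param sd_factor threshold in background-SD units (default 3).
#' @param side `"activated"` or `"inhibited"`.
#' @return logical array of the map's shape.
#' @export
threshold_map <- function(map, sd_factor = 3, side = c("activated", "inhibited")) {
  side <- match.arg(side)
  bg_sd <- stats::mad(map[map != 0], center = 0)
  if (!is.finite(bg_sd) || bg_sd == 0) bg_sd <- stats::sd(map)
  if (side == "activated") map > sd_factor * bg_sd else map < -sd_factor * bg_sd
}
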