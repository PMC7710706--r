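# local maxima of a numeric vector (strictly above both neighbours;
# plateaus take their first index), with topographic prominence
local_maxima_prominence <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(0), prominence = numeric(0)))
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (!is.na(x[i]) && !is.na(x[i - 1]) && x[i] > x[i - 1]) {
      j <- i
      while (j < n && !is.na(x[j + 1]) && x[j + 1] == x[i]) j <- j + 1L
      if (j < n && !is.na(x[j + 1]) && x[j + 1] < x[i]) {
        idx <- c(idx, i)
        i <- j
      }
    }
    i <- i + 1L
  }
  safe_min <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) Inf else min(v)
  }
  prom <- vapply(idx, function(p) {
    h <- x[p]
    # lowest point before meeting a strictly taller sample, on each side
    left <- x[seq_len(p - 1)]
    taller <- which(left > h)
    lo_l <- if (length(taller)) safe_min(left[(max(taller) + 1):(p - 1)])
            else safe_min(left)
    right <- x[(p + 1):length(x)]
    taller <- which(right > h)
    lo_r <- if (length(taller)) safe_min(right[seq_len(min(taller) - 1)])
            else safe_min(right)
    h - max(lo_l, lo_r)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Detect swing peaks from tarsal-tip height
#'
#' The tarsal-tip y trace of one leg is z-scored and its local maxima
#' are taken as swing peaks when their topographic prominence reaches
#' `prominence_z` (in z-units) and they are at least `min_separation_s`
#' apart. When two candidates are closer than the minimum separation the
#' higher one wins.
#'
#' @param pose a [pose_series()], or a numeric height trace.
#' @param leg leg label (ignored when `pose` is a numeric vector).
#' @param prominence_z minimum peak prominence in z-score units
#'   (default 1).
#' @param min_separation_s minimum peak separation in seconds
#'   (default 0.05).
#' @param fps frame rate, required when `pose` is a bare numeric trace.
#' @return a list of class `swing_peak_set`: `peaks` (1-based frame
#'   indices, strictly increasing), `fps`, and the detection parameters.
#' @export
detect_swing_peaks <- function(pose, leg = NULL, prominence_z = 1,
                               min_separation_s = 0.05, fps = NULL) {
  if (inherits(pose, "pose_series")) {
    y <- landmark_xy(pose, paste0(leg, "_tarsal_tip"))[, 2]
    fps <- pose$fps
  } else {
    y <- as.numeric(pose)
    if (is.null(fps)) stop("fps is required for a bare numeric trace")
  }
  if (all(is.na(y))) stop("all-NaN tarsal-tip trace")
  if (length(y) < fps) stop("need at least 1 s of data")
  s <- stats::sd(y, na.rm = TRUE)
  z <- if (s > 0) (y - mean(y, na.rm = TRUE)) / s else y * 0
  cand <- local_maxima_prominence(z)
  cand <- cand[cand$prominence >= prominence_z, , drop = FALSE]
  min_sep <- max(1L, as.integer(round(min_separation_s * fps)))
  # greedy: keep highest candidates first, drop any within min_sep of a kept one
  ord <- order(z[cand$index], decreasing = TRUE)
  kept <- integer(0)
  for (p in cand$index[ord]) {
    if (all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  structure(list(peaks = sort(kept), fps = fps,
                 prominence_z = prominence_z,
                 min_separation_s = min_separation_s),
            class = "swing_peak_set")
}

#' Step frequency from swing peaks
#'
#' Reciprocal of the mean interval between neighbouring swing peaks.
#'
#' @param peaks a `swing_peak_set` from [detect_swing_peaks()], or a
#'   numeric vector of peak frame indices (then `fps` is required).
#' @param fps frame rate for bare index vectors.
#' @return frequency in Hz, or `NA` (with a warning) for < 2 peaks.
#' @export
step_frequency <- function(peaks, fps = NULL) {
  if (inherits(peaks, "swing_peak_set")) {
    fps <- peaks$fps
    peaks <- peaks$peaks
  }
  if (is.null(fps)) stop("fps is required for a bare peak-index vector")
  if (length(peaks) < 2) {
    warning("step_frequency undefined for fewer than 2 swing peaks")
    return(NA_real_)
  }
  1 / mean(diff(peaks) / fps)
}
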