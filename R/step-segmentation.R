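#' Step window specification
#'
#' Defines how step windows are cut around swing peaks: total window
#' length, the number of frames shown before the peak (`placement`, the
#' 0-based window index of the peak), and the truncation margin applied
#' when a neighbouring swing peak falls inside the window.
#'
#' Two named presets ship with the package: `"fig_long"` (300 frames =
#' 1.5 s at 200 fps, peak 40 frames in, 8-frame margin) for slow-flexion
#' quantification, and `"fig_short"` (100 frames = 0.5 s, peak 49 frames
#' in so that 49 frames precede and 50 follow it, 8-frame margin) for
#' step-geometry quantification.
#'
#' @param window window length in frames.
#' @param placement frames before the swing peak (0-based peak index
#'   within the window); `0 <= placement < window`.
#' @param margin frames excluded next to a neighbouring swing peak.
#' @return an object of class `step_window_spec`.
#' @export
step_window_spec <- function(window = 300L, placement = 40L, margin = 8L) {
  window <- as.integer(window); placement <- as.integer(placement)
  margin <- as.integer(margin)
  if (placement < 0 || placement >= window)
    stop("placement must satisfy 0 <= placement < window")
  if (margin < 0) stop("margin must be >= 0")
  structure(list(window = window, placement = placement, margin = margin),
            class = "step_window_spec")
}

#' @param preset `"fig_long"` or `"fig_short"`.
#' @rdname step_window_spec
#' @export
step_window_preset <- function(preset = c("fig_long", "fig_short")) {
  switch(match.arg(preset),
         fig_long = step_window_spec(300L, 40L, 8L),
         fig_short = step_window_spec(100L, 49L, 8L))
}

#' Segment traces into swing-peak-aligned step windows
#'
#' Cuts one window per swing peak from a set of per-frame traces. Each
#' window nominally spans `placement` frames before its peak and
#' `window - placement - 1` frames after it; it is truncated `margin`
#' frames short of a neighbouring swing peak that falls inside it,
#' clipped at the analysis-window boundaries, and never zero-filled.
#' Steps whose peak lies outside the analysis window are dropped and
#' counted.
#'
#' @param traces numeric matrix `frames x channels` with column names
#'   (e.g. `tip_x`, `tip_y`, `femur_tibia`).
#' @param peaks a `swing_peak_set` or a vector of 1-based peak frame
#'   indices.
#' @param spec a [step_window_spec()].
#' @param fps frame rate (taken from `peaks` when it is a
#'   `swing_peak_set`).
#' @param analysis_window optional 1-based inclusive frame range
#'   `c(first, last)` restricting the analysis.
#' @return an object of class `step_ensemble`: `steps` (a list; each
#'   step has `frames`, aligned window positions `pos` (1-based; the
#'   peak sits at `placement + 1`), `peak_frame`, `traces`, and
#'   truncation flags), plus `spec`, `fps`, and `n_dropped`.
#' @export
segment_steps <- function(traces, peaks, spec = step_window_preset("fig_long"),
                          fps = NULL, analysis_window = NULL) {
  if (inherits(peaks, "swing_peak_set")) {
    fps <- peaks$fps
    peaks <- peaks$peaks
  }
  if (is.null(fps)) stop("fps is required")
  if (is.null(dim(traces))) traces <- cbind(trace = as.numeric(traces))
  n <- nrow(traces)
  if (any(peaks < 1 | peaks > n)) stop("swing peaks outside the trace bounds")
  aw <- analysis_window %||% c(1L, n)
  keep <- peaks >= aw[1] & peaks <= aw[2]
  n_dropped <- sum(!keep)
  peaks_in <- peaks[keep]

  steps <- vector("list", length(peaks_in))
  for (i in seq_along(peaks_in)) {
    p <- peaks_in[i]
    start <- p - spec$placement
    end <- start + spec$window - 1L
    # neighbouring peaks (any detected peak, in or out of the window)
    prev_p <- suppressWarnings(max(peaks[peaks < p]))
    next_p <- suppressWarnings(min(peaks[peaks > p]))
    lo <- max(start, aw[1],
              if (is.finite(prev_p)) prev_p + spec$margin + 1L else -Inf)
    hi <- min(end, aw[2],
              if (is.finite(next_p)) next_p - spec$margin - 1L else Inf)
    frames <- seq.int(lo, hi)
    steps[[i]] <- list(frames = frames,
                       pos = frames - start + 1L,
                       peak_frame = p,
                       traces = traces[frames, , drop = FALSE],
                       truncated_pre = lo > start,
                       truncated_post = hi < end)
  }
  structure(list(steps = steps, spec = spec, fps = fps, n_dropped = n_dropped),
            class = "step_ensemble")
}

#' @export
print.step_ensemble <- function(x, ...) {
  cat(sprintf("<step_ensemble> %d steps (window %d, peak at index %d, margin %d), %d dropped\n",
              length(x$steps), x$spec$window, x$spec$placement, x$spec$margin,
              x$n_dropped))
  invisible(x)
}

#' Average aligned steps and infer the swing interval
#'
#' Pointwise mean of all steps at each aligned window position;
#' truncated tails are excluded from the denominator, never zero-filled.
#' The swing interval of the averaged step is inferred from the vertical
#' velocity of the averaged tarsal-tip height: the height trace is
#' smoothed with a local-quadratic (Savitzky-Golay) filter, and the
#' swing spans the contiguous rise (velocity above `vel_frac` of its
#' peak magnitude) leading into the swing peak through the contiguous
#' fall following it.
#'
#' @param ensemble a [segment_steps()] result.
#' @param height_col trace column holding tarsal-tip height (default
#'   `"tip_y"`; swing inference is skipped when absent).
#' @param smooth_n Savitzky-Golay window length in frames (odd,
#'   default 11).
#' @param vel_frac velocity threshold as a fraction of the peak
#'   smoothed-velocity magnitude (default 0.1).
#' @return a list: `mean` (matrix `window x channels`), `n` (per-position
#'   contributor counts), `swing_interval` (1-based inclusive window
#'   positions, or NULL), `spec`, `fps`.
#' @export
average_steps <- function(ensemble, height_col = "tip_y", smooth_n = 11,
                          vel_frac = 0.1) {
  stopifnot(inherits(ensemble, "step_ensemble"))
  if (length(ensemble$steps) == 0) stop("empty step ensemble")
  W <- ensemble$spec$window
  C <- ncol(ensemble$steps[[1]]$traces)
  acc <- matrix(0, W, C)
  cnt <- matrix(0L, W, C)
  for (s in ensemble$steps) {
    v <- s$traces
    ok <- is.finite(v)
    v[!ok] <- 0
    acc[s$pos, ] <- acc[s$pos, ] + v
    cnt[s$pos, ] <- cnt[s$pos, ] + ok
  }
  avg <- acc / cnt
  avg[cnt == 0] <- NA_real_
  colnames(avg) <- colnames(ensemble$steps[[1]]$traces)

  swing <- NULL
  if (!is.null(height_col) && height_col %in% colnames(avg)) {
    swing <- infer_swing_interval(avg[, height_col],
                                  peak_pos = ensemble$spec$placement + 1L,
                                  smooth_n = smooth_n, vel_frac = vel_frac)
  }
  list(mean = avg, n = cnt[, 1], swing_interval = swing,
       spec = ensemble$spec, fps = ensemble$fps)
}

# swing interval from an averaged height trace: contiguous rise into the
# peak plus contiguous fall after it, thresholded at vel_frac * max |v|
infer_swing_interval <- function(height, peak_pos, smooth_n = 11,
                                 vel_frac = 0.1) {
  ok <- which(is.finite(height))
  if (length(ok) < smooth_n) return(NULL)
  seg <- ok[1]:ok[length(ok)]
  h <- height[seg]
  if (anyNA(h)) h <- stats::approx(seq_along(h), h, seq_along(h), rule = 2)$y
  v <- signal::sgolayfilt(h, p = 2, n = smooth_n, m = 1)
  th <- vel_frac * max(abs(v))
  if (th == 0) return(NULL)
  p <- peak_pos - seg[1] + 1L
  p <- min(max(p, 1L), length(v))
  # last super-threshold rise sample at or before the peak, extended back
  rise <- which(v[seq_len(p)] > th)
  i <- if (length(rise)) max(rise) else p
  while (i > 1 && v[i - 1] > th) i <- i - 1
  # first sub-threshold fall sample at or after the peak, extended forward
  fall <- which(v[p:length(v)] < -th)
  j <- if (length(fall)) p + min(fall) - 1L else p
  while (j < length(v) && v[j + 1] < -th) j <- j + 1
  c(start = seg[1] + i - 1L, end = seg[1] + j - 1L)
}
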