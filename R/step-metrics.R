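#' Step geometry: extreme positions, step size, swing-stroke amplitude
#'
#' From a tarsal-tip trajectory of one step (analysis frame: x anterior,
#' y up), the anterior extreme position (AEP) is the maximal-x point,
#' the posterior extreme position (PEP) the minimal-x point, and the
#' dorsal extreme position (DEP) the maximal-y point. Step size is the
#' Euclidean distance between AEP and PEP; swing-stroke amplitude is the
#' distance from DEP to the closed line segment joining AEP and PEP.
#'
#' @param trajectory numeric matrix `frames x 2` of tip (x, y).
#' @return a list of class `step_geometry`: `aep`, `pep`, `dep`,
#'   `step_size`, `swing_stroke_amplitude`, and `degenerate` (TRUE with
#'   `swing_stroke_amplitude = NA` when fewer than 3 distinct points).
#' @export
step_geometry <- function(trajectory) {
  trajectory <- as.matrix(trajectory)
  if (nrow(trajectory) == 0) stop("empty trajectory")
  stopifnot(ncol(trajectory) == 2)
  trajectory <- trajectory[stats::complete.cases(trajectory), , drop = FALSE]
  if (nrow(trajectory) == 0) stop("trajectory has no finite points")
  aep <- trajectory[which.max(trajectory[, 1]), ]
  pep <- trajectory[which.min(trajectory[, 1]), ]
  dep <- trajectory[which.max(trajectory[, 2]), ]
  degenerate <- nrow(unique(trajectory)) < 3
  amp <- if (degenerate) NA_real_ else point_segment_distance(dep, aep, pep)
  if (degenerate) warning("fewer than 3 distinct points: swing-stroke amplitude undefined")
  structure(list(aep = aep, pep = pep, dep = dep,
                 step_size = sqrt(sum((aep - pep)^2)),
                 swing_stroke_amplitude = amp,
                 degenerate = degenerate),
            class = "step_geometry")
}

#' Joint-angle range over a step
#'
#' Maximum minus minimum of an angle trace, ignoring missing frames.
#'
#' @param angle_trace numeric vector (degrees).
#' @return range in degrees (>= 0), or `NA` if no finite frames.
#' @export
joint_angle_range <- function(angle_trace) {
  x <- angle_trace[is.finite(angle_trace)]
  if (length(x) == 0) return(NA_real_)
  max(x) - min(x)
}

#' Maximal joint flexion after stimulus onset
#'
#' Minimum joint angle reached within `window_s` seconds after stimulus
#' onset, evaluated only up to the first re-extension: scanning forward,
#' the running minimum is frozen as soon as the angle rises more than
#' `reextension_deg` above it. A later, deeper dip after a re-extension
#' is therefore ignored.
#'
#' @param angle_trace full angle trace (degrees).
#' @param fps frame rate.
#' @param onset_s stimulus onset time (s, 0 = first frame).
#' @param window_s evaluation window after onset (default 1 s).
#' @param reextension_deg rise above the running minimum that counts as
#'   re-extension (default 5 degrees).
#' @return minimal pre-re-extension angle in degrees.
#' @export
max_flexion <- function(angle_trace, fps, onset_s, window_s = 1,
                        reextension_deg = 5) {
  i0 <- as.integer(round(onset_s * fps)) + 1L
  i1 <- i0 + as.integer(round(window_s * fps)) - 1L
  if (i0 < 1 || i1 > length(angle_trace))
    stop("trace does not cover the [onset, onset + window] interval")
  w <- angle_trace[i0:i1]
  if (all(!is.finite(w))) stop("all-NaN angle window")
  m <- Inf
  for (v in w) {
    if (!is.finite(v)) next
    if (v < m) m <- v
    else if (v >= m + reextension_deg) break
  }
  m
}

#' Minimal joint angle before the swing peak of a step
#'
#' Minimum of an angle trace over the pre-peak portion of a step window
#' (stance-phase flexion depth shortly before lift-off).
#'
#' @param step_angle_trace angle trace of one aligned step (degrees).
#' @param peak_pos 1-based position of the swing peak within the trace.
#' @return minimum angle in degrees, or `NA` (with a warning) when the
#'   peak sits at the first frame.
#' @export
min_step_angle <- function(step_angle_trace, peak_pos) {
  if (peak_pos <= 1) {
    warning("swing peak at step start: pre-peak minimum undefined")
    return(NA_real_)
  }
  pre <- step_angle_trace[seq_len(peak_pos - 1L)]
  pre <- pre[is.finite(pre)]
  if (length(pre) == 0) return(NA_real_)
  min(pre)
}

#' Flexion slope of an averaged step angle trace
#'
#' Ordinary least-squares line fit of the averaged joint angle over its
#' declining phase, from the position of the maximal angle to the end of
#' the step window. The slope quantifies flexion speed in degrees per
#' second (negative for flexion).
#'
#' @param avg_angle_trace averaged angle trace over the step window
#'   (degrees).
#' @param fps frame rate.
#' @return slope in degrees/s.
#' @export
flexion_slope <- function(avg_angle_trace, fps) {
  ok <- which(is.finite(avg_angle_trace))
  if (length(ok) < 2) stop("fewer than 2 finite points in the angle trace")
  start <- ok[which.max(avg_angle_trace[ok])]
  idx <- ok[ok >= start]
  if (length(idx) < 2) stop("fewer than 2 points between the angle maximum and the window end")
  t_s <- (idx - 1) / fps
  unname(stats::coef(stats::lm(avg_angle_trace[idx] ~ t_s))[2])
}
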