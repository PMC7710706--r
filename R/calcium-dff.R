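#' ROI dF/F0 traces per session and session-averaged
#'
#' For each session, the ROI fluorescence `F(t)` is the mean intensity
#' over the ROI voxels; the baseline `F0` is the mean of `F` over the
#' early baseline volumes (default volumes 2-9, before the first
#' stimulus), and `dF/F = (F - F0)/F0`. The session-averaged trace is
#' the mean across sessions. dF/F is invariant under any positive gain
#' applied to the raw recording.
#'
#' @param rec a [sample_recording()].
#' @param roi logical `Z x Y x X` array, or an n x 3 integer matrix of
#'   (z, y, x) voxel indices, or a list `list(z = <plane>, polygon =
#'   <n x 2 matrix of (y, x) vertices>)` defining a polygon ROI on a
#'   single imaging plane.
#' @param baseline_frames volume indices used for F0 (default `2:9`).
#' @return an object of class `dff_trace`: `per_session` (sessions x T
#'   matrix), `f0` (per-session baselines), `average` (length-T trace).
#' @export
roi_dff <- function(rec, roi, baseline_frames = 2:9) {
  stopifnot(inherits(rec, "sample_recording"))
  d <- dim(rec$sessions[[1]])[2:4]
  vox <- roi_voxels(roi, d)
  if (nrow(vox) == 0) stop("empty ROI")
  nt <- dim(rec$sessions[[1]])[1]
  if (any(baseline_frames < 1 | baseline_frames > nt))
    stop("baseline frames outside the session")
  lin <- (vox[, 3] - 1) * d[1] * d[2] + (vox[, 2] - 1) * d[1] + vox[, 1]
  per <- t(vapply(rec$sessions, function(s) {
    dim(s) <- c(nt, prod(d))
    rowMeans(s[, lin, drop = FALSE])
  }, numeric(nt)))
  f0 <- rowMeans(per[, baseline_frames, drop = FALSE])
  if (any(f0 <= 0)) stop("non-positive baseline F0")
  dff <- (per - f0) / f0
  structure(list(per_session = dff, f0 = f0, average = colMeans(dff)),
            class = "dff_trace")
}

# normalize the accepted ROI encodings to an n x 3 (z, y, x) index matrix
roi_voxels <- function(roi, dims) {
  if (is.list(roi) && !is.null(roi$polygon)) {
    z <- roi$z
    if (z < 1 || z > dims[1]) stop("ROI plane outside the volume")
    poly <- roi$polygon
    yy <- rep(seq_len(dims[2]), times = dims[3])
    xx <- rep(seq_len(dims[3]), each = dims[2])
    inside <- points_in_polygon(yy, xx, poly[, 1], poly[, 2])
    return(cbind(z = z, y = yy[inside], x = xx[inside]))
  }
  if (is.array(roi) && is.logical(roi)) {
    if (!identical(dim(roi), as.integer(dims)) && !identical(dim(roi), dims))
      stop("ROI mask shape does not match the volume")
    return(which(roi, arr.ind = TRUE))
  }
  roi <- as.matrix(roi)
  if (ncol(roi) != 3) stop("ROI index matrix must have 3 columns (z, y, x)")
  if (any(roi < 1) || any(roi[, 1] > dims[1]) || any(roi[, 2] > dims[2]) ||
      any(roi[, 3] > dims[3]))
    stop("ROI voxel indices outside the volume")
  roi
}

# even-odd rule point-in-polygon test, vectorized over query points
points_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Build a response kernel from ROI dF/F traces
#'
#' Pointwise mean of session-averaged dF/F traces from ROIs that respond
#' strongly with short delay; the result serves as the reference signal
#' for voxelwise cross-covariance mapping. No smoothing is applied by
#' default.
#'
#' @param traces a list of [roi_dff()] results (their `average` traces
#'   are used), a list of numeric traces, or a matrix with one trace per
#'   row.
#' @param protocol_tag label recording which stimulus protocol the
#'   kernel belongs to.
#' @param smooth_n optional odd Savitzky-Golay window (frames); `NULL`
#'   (default) disables smoothing.
#' @return an object of class `response_kernel`.
#' @export
build_kernel <- function(traces, protocol_tag = "custom", smooth_n = NULL) {
  if (is.matrix(traces)) traces <- asplit(traces, 1)
  traces <- lapply(traces, function(tr)
    if (inherits(tr, "dff_trace")) tr$average else as.numeric(tr))
  len <- unique(vapply(traces, length, integer(1)))
  if (length(len) != 1) stop("all traces must have equal length")
  k <- rowMeans(do.call(cbind, traces))
  if (!is.null(smooth_n)) k <- signal::sgolayfilt(k, p = 2, n = smooth_n)
  structure(list(trace = k, protocol_tag = protocol_tag, volume_rate = NA_real_),
            class = "response_kernel")
}
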