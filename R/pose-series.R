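#' Pose time series
#'
#' Per-frame 2-D landmark coordinates plus a tracking-confidence value in
#' `[0, 1]` for each landmark, with the acquisition frame rate. The
#' analysis frame is x positive toward anterior and y up (dorsal
#' positive); readers of image-coordinate files are responsible for
#' flipping y.
#'
#' @param coords numeric array `frames x landmarks x 2` with landmark
#'   dimnames; last dimension is (x, y).
#' @param confidence numeric matrix `frames x landmarks` in `[0, 1]`;
#'   defaults to all 1.
#' @param fps frames per second (> 0).
#' @return an object of class `pose_series`.
#' @export
pose_series <- function(coords, confidence = NULL, fps) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 2, fps > 0)
  if (is.null(dimnames(coords)[[2]]))
    stop("coords must carry landmark names on dimension 2")
  if (is.null(confidence))
    confidence <- matrix(1, dim(coords)[1], dim(coords)[2])
  stopifnot(all(dim(confidence) == dim(coords)[1:2]))
  colnames(confidence) <- dimnames(coords)[[2]]
  structure(list(coords = coords, confidence = confidence, fps = fps),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> %d frames x %d landmarks @ %g fps (%.2f s)\n",
              n_frames(x), dim(x$coords)[2], x$fps, n_frames(x) / x$fps))
  invisible(x)
}

n_frames <- function(pose) dim(pose$coords)[1]

landmark_names <- function(pose) dimnames(pose$coords)[[2]]

# frames x 2 matrix of one landmark's coordinates
landmark_xy <- function(pose, name) {
  if (!name %in% landmark_names(pose))
    stop("landmark not present in pose series: ", name)
  matrix(pose$coords[, name, ], ncol = 2)
}

landmark_conf <- function(pose, name) pose$confidence[, name]

#' Footfall pattern
#'
#' Boolean swing/stance matrix, one row per leg, one column per frame
#' (`TRUE` = swing). The integration unit is the frame.
#'
#' @param mask logical matrix legs x frames with leg rownames.
#' @param fps frames per second.
#' @return an object of class `footfall_pattern`.
#' @export
footfall_pattern <- function(mask, fps) {
  stopifnot(is.matrix(mask), is.logical(mask), fps > 0)
  if (is.null(rownames(mask))) stop("mask must carry leg rownames")
  if (anyDuplicated(rownames(mask))) stop("leg labels must be unique")
  structure(list(mask = mask, fps = fps), class = "footfall_pattern")
}

#' @export
print.footfall_pattern <- function(x, ...) {
  cat(sprintf("<footfall_pattern> %d legs x %d frames @ %g fps, swing fraction %.2f\n",
              nrow(x$mask), ncol(x$mask), x$fps, mean(x$mask)))
  invisible(x)
}
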