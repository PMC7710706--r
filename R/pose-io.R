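#' Read a pose table in the DeepLabCut CSV dialect
#'
#' Expects the three header rows (`scorer` / `bodyparts` / `coords`) and,
#' per landmark, an `x`, `y`, `likelihood` column triplet; the first
#' column is the frame index. Image-coordinate y (down-positive) is
#' flipped into the y-up analysis frame. A plain single-header table with
#' `<landmark>_x`, `<landmark>_y`, `<landmark>_conf` columns is also
#' accepted.
#'
#' @param path CSV file path.
#' @param fps acquisition frame rate (not stored in the format).
#' @param required_landmarks landmark names that must be present, e.g.
#'   `leg_landmarks("LF")`; checked after parsing.
#' @param flip_y flip image y to the y-up analysis frame (default TRUE).
#' @return a [pose_series()].
#' @export
read_pose_table <- function(path, fps = 200, required_landmarks = NULL,
                            flip_y = TRUE) {
  head3 <- utils::read.csv(path, header = FALSE, nrows = 3,
                           colClasses = "character")
  if (identical(tolower(head3[1, 1]), "scorer") &&
      identical(tolower(head3[2, 1]), "bodyparts") &&
      identical(tolower(head3[3, 1]), "coords")) {
    parts <- as.character(head3[2, -1])
    kinds <- tolower(as.character(head3[3, -1]))
    if (length(parts) %% 3 != 0 ||
        !all(kinds == rep(c("x", "y", "likelihood"), length(parts) / 3)))
      stop("malformed DeepLabCut header: expected x,y,likelihood triplets")
    dat <- utils::read.csv(path, header = FALSE, skip = 3)
    if (!all(vapply(dat[-1], is.numeric, logical(1))))
      stop("non-numeric cells in pose table body")
    lms <- unique(parts)
    if (!all(table(parts) == 3)) stop("each bodypart needs exactly one x,y,likelihood triplet")
    n <- nrow(dat)
    coords <- array(NA_real_, c(n, length(lms), 2),
                    dimnames = list(NULL, lms, c("x", "y")))
    conf <- matrix(NA_real_, n, length(lms), dimnames = list(NULL, lms))
    for (j in seq_along(lms)) {
      cols <- 1L + which(parts == lms[j])  # offset for the index column
      coords[, j, 1] <- dat[[cols[1]]]
      coords[, j, 2] <- if (flip_y) -dat[[cols[2]]] else dat[[cols[2]]]
      conf[, j] <- dat[[cols[3]]]
    }
  } else {
    dat <- utils::read.csv(path, header = TRUE, check.names = FALSE)
    xs <- grep("_x$", names(dat), value = TRUE)
    lms <- sub("_x$", "", xs)
    if (length(lms) == 0) stop("malformed header: no DeepLabCut rows and no *_x columns")
    n <- nrow(dat)
    coords <- array(NA_real_, c(n, length(lms), 2),
                    dimnames = list(NULL, lms, c("x", "y")))
    conf <- matrix(1, n, length(lms), dimnames = list(NULL, lms))
    for (j in seq_along(lms)) {
      ycol <- paste0(lms[j], "_y")
      if (!ycol %in% names(dat)) stop("missing column: ", ycol)
      coords[, j, 1] <- dat[[paste0(lms[j], "_x")]]
      coords[, j, 2] <- if (flip_y) -dat[[ycol]] else dat[[ycol]]
      ccol <- paste0(lms[j], "_conf")
      if (ccol %in% names(dat)) conf[, j] <- dat[[ccol]]
    }
  }
  if (!is.null(required_landmarks)) {
    missing <- setdiff(required_landmarks, lms)
    if (length(missing) > 0)
      stop("pose table is missing required landmarks: ",
           paste(missing, collapse = ", "))
  }
  pose_series(coords, conf, fps = fps)
}

#' Write a pose series in the DeepLabCut CSV dialect
#'
#' Inverse of [read_pose_table()]: emits the three header rows and one
#' `x`, `y`, `likelihood` triplet per landmark, negating y back into
#' image coordinates so that a read/write round trip is exact.
#'
#' @param pose a [pose_series()].
#' @param path output CSV path.
#' @param scorer scorer tag placed in the first header row.
#' @param flip_y negate y on output (default TRUE, matching the reader).
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(pose, path, scorer = "walkback", flip_y = TRUE) {
  lms <- landmark_names(pose)
  n <- n_frames(pose)
  cols <- vector("list", 3 * length(lms))
  for (j in seq_along(lms)) {
    y <- pose$coords[, j, 2]
    cols[[3 * j - 2]] <- pose$coords[, j, 1]
    cols[[3 * j - 1]] <- if (flip_y) -y else y
    cols[[3 * j]] <- pose$confidence[, j]
  }
  body <- do.call(cbind, cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, 3 * length(lms))), collapse = ","), con)
  writeLines(paste(c("bodyparts", rep(lms, each = 3)), collapse = ","), con)
  writeLines(paste(c("coords", rep(c("x", "y", "likelihood"), length(lms))),
                   collapse = ","), con)
  utils::write.table(cbind(0:(n - 1), body), con, sep = ",", col.names = FALSE,
                     row.names = FALSE)
  invisible(path)
}
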