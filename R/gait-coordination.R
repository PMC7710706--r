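#' Swing/stance footfall pattern from pose or annotations
#'
#' Builds a [footfall_pattern()] either from tarsal-tip height (method
#' `"height"`) or by passing through a per-frame annotation table
#' (method `"labels"`: a logical matrix or data frame, frames x legs;
#' never despeckled).
#'
#' The height method detects swing bouts where the z-scored tip height
#' exceeds `threshold_z`, removes bouts (and gaps) shorter than
#' `min_bout` frames, and then refines each bout's boundaries: the bout
#' is extended outward along the strictly descending flanks of the
#' height trace (lift-off and touch-down edges) and trailing frames
#' that already sit on the ground plateau are trimmed. On clean traces
#' this recovers swing/stance transitions to within one frame of the
#' lift-off and touch-down events.
#'
#' @param x a [pose_series()] (method `"height"`) or a frames x legs
#'   logical annotation (method `"labels"`).
#' @param method `"height"` or `"labels"`.
#' @param legs leg labels to score (default all six).
#' @param threshold_z swing threshold on z-scored tip height (default
#'   0.5).
#' @param min_bout minimum bout length in frames for despeckling
#'   (default 3).
#' @param fps frame rate, required for method `"labels"`.
#' @return a [footfall_pattern()].
#' @export
swing_mask <- function(x, method = c("height", "labels"), legs = LEG_LABELS,
                       threshold_z = 0.5, min_bout = 3L, fps = NULL) {
  method <- match.arg(method)
  if (method == "labels") {
    if (is.null(fps)) stop("fps is required for annotation input")
    m <- as.matrix(x)
    if (is.null(colnames(m))) stop("annotation table must carry leg column names")
    unknown <- setdiff(colnames(m), LEG_LABELS)
    if (length(unknown) > 0)
      stop("unknown leg labels: ", paste(unknown, collapse = ", "))
    mode(m) <- "logical"
    return(footfall_pattern(t(m), fps))
  }
  stopifnot(inherits(x, "pose_series"))
  unknown <- setdiff(legs, LEG_LABELS)
  if (length(unknown) > 0)
    stop("unknown leg labels: ", paste(unknown, collapse = ", "))
  mask <- matrix(FALSE, length(legs), n_frames(x), dimnames = list(legs, NULL))
  for (leg in legs) {
    y <- landmark_xy(x, paste0(leg, "_tarsal_tip"))[, 2]
    s <- stats::sd(y, na.rm = TRUE)
    z <- if (s > 0) (y - mean(y, na.rm = TRUE)) / s else y * 0
    sw <- !is.na(z) & z > threshold_z
    sw <- despeckle(sw, min_bout)
    mask[leg, ] <- refine_swing_bouts(sw, y)
  }
  footfall_pattern(mask, x$fps)
}

# extend each swing bout outward while the height trace keeps strictly
# descending away from it, then trim frames lying on the outside plateau
refine_swing_bouts <- function(sw, y) {
  if (!any(sw)) return(sw)
  n <- length(sw)
  r <- rle(sw)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- rep(FALSE, n)
  for (i in which(r$values)) {
    a <- starts[i]
    b <- ends[i]
    while (a > 1 && !is.na(y[a - 1]) && !is.na(y[a]) && y[a - 1] < y[a]) a <- a - 1L
    while (b < n && !is.na(y[b + 1]) && !is.na(y[b]) && y[b + 1] < y[b]) b <- b + 1L
    while (b > a && b < n && !is.na(y[b + 1]) && y[b] == y[b + 1]) b <- b - 1L
    out[a:b] <- TRUE
  }
  out
}

#' Co-swing index of a leg pair
#'
#' Fraction of time two legs swing together: frames where both legs are
#' in swing divided by frames where either is, over a half-open frame
#' window `[start, end)`. Symmetric in its leg arguments and bounded in
#' `[0, 1]`.
#'
#' @param pattern a [footfall_pattern()].
#' @param legA,legB leg labels.
#' @param window 1-based half-open frame window `c(start, end)`;
#'   default: the full recording.
#' @return the index in `[0, 1]`, or `NA` (with a warning) when neither
#'   leg swings in the window.
#' @export
co_swing_index <- function(pattern, legA, legB, window = NULL) {
  stopifnot(inherits(pattern, "footfall_pattern"))
  for (leg in c(legA, legB))
    if (!leg %in% rownames(pattern$mask)) stop("unknown leg label: ", leg)
  nf <- ncol(pattern$mask)
  window <- window %||% c(1L, nf + 1L)
  if (window[1] < 1 || window[2] > nf + 1L || window[2] <= window[1])
    stop("window out of recording bounds")
  idx <- seq.int(window[1], window[2] - 1L)
  a <- pattern$mask[legA, idx]
  b <- pattern$mask[legB, idx]
  either <- sum(a | b)
  if (either == 0) {
    warning("neither leg swings in the window: co-swing index undefined")
    return(NA_real_)
  }
  sum(a & b) / either
}

#' Classify a leg pair
#'
#' Laterality (ipsilateral / contralateral) and segmental relation
#' (intrasegmental = same leg segment pair, e.g. both forelegs;
#' intersegmental otherwise).
#'
#' @param legA,legB leg labels (side letter then segment letter).
#' @return list with `pair`, `laterality`, `segmental`.
#' @export
classify_pair <- function(legA, legB) {
  if (legA == legB) stop("a pair requires two distinct legs")
  list(pair = c(legA, legB),
       laterality = if (substr(legA, 1, 1) == substr(legB, 1, 1))
         "ipsilateral" else "contralateral",
       segmental = if (substr(legA, 2, 2) == substr(legB, 2, 2))
         "intrasegmental" else "intersegmental")
}

#' Co-swing indices of all leg pairs, with class grouping
#'
#' Scores all unordered leg pairs in a footfall pattern and groups the
#' indices into coordination classes. The default grouping separates
#' intrasegmental pairs from intersegmental ones and splits the latter
#' by laterality; pass `grouping = "segmental"` to pool all
#' intersegmental pairs.
#'
#' @param pattern a [footfall_pattern()].
#' @param window half-open frame window as in [co_swing_index()].
#' @param grouping `"laterality"` (default) or `"segmental"`.
#' @return list with `pairs` (data frame: legA, legB, laterality,
#'   segmental, class, co_swing) and `class_means` (named mean index per
#'   class, NA pairs dropped).
#' @export
pairwise_summary <- function(pattern, window = NULL,
                             grouping = c("laterality", "segmental")) {
  stopifnot(inherits(pattern, "footfall_pattern"))
  grouping <- match.arg(grouping)
  legs <- rownames(pattern$mask)
  if (length(legs) < 2) stop("need at least 2 legs")
  combos <- utils::combn(legs, 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    cl <- classify_pair(a, b)
    idx <- suppressWarnings(co_swing_index(pattern, a, b, window))
    grp <- if (cl$segmental == "intrasegmental") "intrasegmental"
           else if (grouping == "segmental") "intersegmental"
           else paste0("intersegmental_", cl$laterality)
    data.frame(legA = a, legB = b, laterality = cl$laterality,
               segmental = cl$segmental, class = grp, co_swing = idx,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  ok <- !is.na(pairs$co_swing)
  class_means <- tapply(pairs$co_swing[ok], pairs$class[ok], mean)
  list(pairs = pairs, class_means = class_means)
}
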