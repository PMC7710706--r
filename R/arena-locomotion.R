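#' Arena stimulus episode schedule
#'
#' Onsets and durations (seconds) of the red-light episodes of an arena
#' assay, plus the pre-stimulus window used for spontaneous forward
#' walking. The `"flybowl9x5"` preset is nine 5-s episodes at 60-s
#' onset-to-onset spacing, the first at 60 s, with a 45-s pre-stimulus
#' window.
#'
#' @param preset `"flybowl9x5"`, or `NULL` to give onsets/durations
#'   directly.
#' @param onsets_s,durations_s episode onsets and durations (s).
#' @param pre_window_s pre-stimulus window length (s, from recording
#'   start).
#' @return an object of class `episode_schedule`.
#' @export
episode_schedule <- function(preset = "flybowl9x5", onsets_s = NULL,
                             durations_s = NULL, pre_window_s = 45) {
  if (!is.null(preset) && is.null(onsets_s)) {
    stopifnot(identical(preset, "flybowl9x5"))
    onsets_s <- 60 * (1:9)
    durations_s <- rep(5, 9)
  }
  stopifnot(length(onsets_s) == length(durations_s), all(durations_s > 0))
  o <- order(onsets_s)
  onsets_s <- onsets_s[o]
  durations_s <- durations_s[o]
  if (any(utils::head(onsets_s + durations_s, -1) > utils::tail(onsets_s, -1)))
    stop("episodes must not overlap")
  structure(list(onsets_s = onsets_s, durations_s = durations_s,
                 pre_window_s = pre_window_s),
            class = "episode_schedule")
}

#' Centroid track of one fly
#'
#' Per-frame arena position (mm) and heading (radians, direction the
#' fly faces) at a nominal frame rate.
#'
#' @param x,y,heading equal-length numeric vectors.
#' @param fps frames per second (default 30).
#' @param fly_id identifier.
#' @return an object of class `centroid_track`.
#' @export
centroid_track <- function(x, y, heading, fps = 30, fly_id = "fly1") {
  stopifnot(length(x) == length(y), length(x) == length(heading), fps > 0)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("positions must be finite")
  if (any(!is.finite(heading))) stop("heading must be defined every frame")
  structure(list(fly_id = fly_id, x = x, y = y, heading = heading, fps = fps),
            class = "centroid_track")
}

#' Heading-projected per-frame speed
#'
#' Projects the frame-to-frame centroid displacement onto the fly's
#' heading: positive values are forward translation, negative backward;
#' pure sideslip contributes zero. The displacement from frame `t` to
#' `t + 1` is assigned frame `t`'s heading, and `dt = 1/fps`.
#'
#' @param track a [centroid_track()].
#' @return numeric vector of length `n_frames - 1` (mm/s); element `t`
#'   covers the interval starting at frame `t`.
#' @export
heading_speed <- function(track) {
  stopifnot(inherits(track, "centroid_track"))
  n <- length(track$x)
  if (n < 2) stop("need at least 2 frames")
  dx <- diff(track$x)
  dy <- diff(track$y)
  h <- track$heading[-n]
  (dx * cos(h) + dy * sin(h)) * track$fps
}

# frame indices (of the speed vector) whose interval start lies in [a, b)
frames_in_window <- function(n_speed, fps, a, b) {
  t0 <- (seq_len(n_speed) - 1) / fps
  which(t0 >= a & t0 < b)
}

#' Cumulative backward walking distance during stimulus episodes
#'
#' Integrates `|v| * dt` over all episode frames whose heading-projected
#' speed is at or below `-threshold`; slower frames contribute nothing.
#'
#' @param track a [centroid_track()].
#' @param schedule an [episode_schedule()].
#' @param threshold backward speed threshold (mm/s, default 1.5).
#' @return distance in mm (>= 0).
#' @export
backward_distance <- function(track, schedule, threshold = 1.5) {
  stopifnot(inherits(schedule, "episode_schedule"))
  v <- heading_speed(track)
  end_s <- max(schedule$onsets_s + schedule$durations_s)
  if (length(v) / track$fps < end_s)
    stop("track shorter than the episode schedule")
  total <- 0
  for (i in seq_along(schedule$onsets_s)) {
    idx <- frames_in_window(length(v), track$fps, schedule$onsets_s[i],
                            schedule$onsets_s[i] + schedule$durations_s[i])
    vv <- v[idx]
    total <- total + sum(abs(vv[vv <= -threshold])) / track$fps
  }
  total
}

#' Net forward walking distance in the pre-stimulus window
#'
#' Signed integral of the heading-projected speed over the pre-stimulus
#' window (no threshold); backward motion cancels forward motion.
#'
#' @param track a [centroid_track()].
#' @param window_s window length from recording start (s, default 45).
#' @return net distance in mm.
#' @export
forward_distance <- function(track, window_s = 45) {
  v <- heading_speed(track)
  if (length(v) / track$fps < window_s)
    stop("window exceeds the track")
  idx <- frames_in_window(length(v), track$fps, 0, window_s)
  sum(v[idx]) / track$fps
}

#' Per-fly distances and cohort summary
#'
#' Computes forward (pre-stimulus) and backward (episode) distances for
#' every track and summarizes the cohort as mean +/- s.e.m.
#'
#' @param tracks list of [centroid_track()].
#' @param schedule an [episode_schedule()].
#' @param threshold backward speed threshold (mm/s).
#' @return list: `per_fly` (data frame: fly_id, forward_mm,
#'   backward_mm), `cohort` (data frame of mean and sem per metric;
#'   s.e.m. is `NA` for a single fly).
#' @export
cohort_summary <- function(tracks, schedule = episode_schedule(),
                           threshold = 1.5) {
  stopifnot(length(tracks) >= 1)
  per_fly <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(fly_id = tr$fly_id,
               forward_mm = forward_distance(tr, schedule$pre_window_s),
               backward_mm = backward_distance(tr, schedule, threshold),
               stringsAsFactors = FALSE)))
  sem <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  cohort <- data.frame(metric = c("forward_mm", "backward_mm"),
                       mean = c(mean(per_fly$forward_mm), mean(per_fly$backward_mm)),
                       sem = c(sem(per_fly$forward_mm), sem(per_fly$backward_mm)))
  list(per_fly = per_fly, cohort = cohort)
}

#' Read and write arena centroid tracks as flat CSV
#'
#' Columns: `fly_id, frame, x_mm, y_mm, heading_rad`; one row per fly
#' per frame, frames 0-based and contiguous per fly.
#'
#' @param tracks list of [centroid_track()].
#' @param path CSV path.
#' @param fps frame rate to attach on read (not stored in the format).
#' @return the writer returns `path` invisibly; the reader a list of
#'   [centroid_track()].
#' @export
write_arena_csv <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(fly_id = tr$fly_id, frame = seq_along(tr$x) - 1L,
               x_mm = tr$x, y_mm = tr$y, heading_rad = tr$heading)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arena_csv
#' @export
read_arena_csv <- function(path, fps = 30) {
  dat <- utils::read.csv(path)
  need <- c("fly_id", "frame", "x_mm", "y_mm", "heading_rad")
  if (!all(need %in% names(dat)))
    stop("arena CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(dat, dat$fly_id), function(d) {
    d <- d[order(d$frame), ]
    centroid_track(d$x_mm, d$y_mm, d$heading_rad, fps = fps,
                   fly_id = as.character(d$fly_id[1]))
  })
}
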