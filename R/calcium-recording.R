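#' Volumetric calcium imaging recording of one sample
#'
#' An ordered list of imaging sessions, each a `T x Z x Y x X` intensity
#' array acquired under the same [stimulus_protocol()].
#'
#' @param sessions list of 4-D arrays, all the same shape, non-negative.
#' @param protocol a [stimulus_protocol()]; `session_volumes` must equal
#'   the sessions' T.
#' @param voxel_size_um optional numeric length-3 voxel size.
#' @return an object of class `sample_recording`.
#' @export
sample_recording <- function(sessions, protocol, voxel_size_um = NULL) {
  stopifnot(length(sessions) >= 1, inherits(protocol, "stimulus_protocol"))
  d1 <- dim(sessions[[1]])
  if (length(d1) != 4) stop("each session must be a T x Z x Y x X array")
  for (s in sessions)
    if (!identical(dim(s), d1)) stop("all sessions must share the same shape")
  if (d1[1] != protocol$session_volumes)
    stop("session length does not match the protocol")
  structure(list(sessions = sessions, protocol = protocol,
                 voxel_size_um = voxel_size_um),
            class = "sample_recording")
}

#' @export
print.sample_recording <- function(x, ...) {
  d <- dim(x$sessions[[1]])
  cat(sprintf("<sample_recording> %d sessions of %d volumes (Z=%d, Y=%d, X=%d)\n",
              length(x$sessions), d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Concatenate imaging sessions into a hyperstack
#'
#' Temporal concatenation in acquisition order; 10 sessions of 60
#' volumes yield a 600-volume hyperstack. Session boundaries are
#' recorded in the `session_starts` attribute.
#'
#' @param rec a [sample_recording()] or a list of 4-D session arrays.
#' @return a `(sum T) x Z x Y x X` array with attributes
#'   `session_starts` (1-based first volume of each session) and
#'   `n_sessions`.
#' @export
concat_sessions <- function(rec) {
  sessions <- if (inherits(rec, "sample_recording")) rec$sessions else rec
  d <- dim(sessions[[1]])
  for (s in sessions)
    if (!identical(dim(s), d)) stop("session shape mismatch")
  nt <- d[1]
  out <- array(NA_real_, c(nt * length(sessions), d[2], d[3], d[4]))
  for (i in seq_along(sessions))
    out[((i - 1) * nt + 1):(i * nt), , , ] <- sessions[[i]]
  attr(out, "session_starts") <- (seq_along(sessions) - 1L) * nt + 1L
  attr(out, "n_sessions") <- length(sessions)
  out
}

#' Split a hyperstack back into equal-length sessions
#'
#' Inverse of [concat_sessions()].
#'
#' @param hyperstack a 4-D array.
#' @param n_sessions number of equal-length sessions.
#' @return list of session arrays.
#' @export
split_sessions <- function(hyperstack, n_sessions) {
  nt <- dim(hyperstack)[1]
  if (nt %% n_sessions != 0) stop("hyperstack length not divisible by n_sessions")
  per <- nt / n_sessions
  lapply(seq_len(n_sessions), function(i)
    hyperstack[((i - 1) * per + 1):(i * per), , , , drop = FALSE])
}

# circular shift of a matrix by s = c(dy, dx): out[i, j] = m[i - dy, j - dx]
circshift2 <- function(m, s) {
  n <- dim(m)
  i <- ((seq_len(n[1]) - 1 - s[1]) %% n[1]) + 1
  j <- ((seq_len(n[2]) - 1 - s[2]) %% n[2]) + 1
  m[i, j, drop = FALSE]
}

#' Rigid translational motion correction of a hyperstack
#'
#' For every volume and z-slice, finds the integer in-plane translation
#' that maximizes the circular cross-correlation (via FFT phase
#' correlation) with the corresponding slice of a reference volume, and
#' applies it. Intended as a lightweight correction for slow in-plane
#' drift; sub-pixel and non-rigid motion are out of scope.
#'
#' @param hyperstack `T x Z x Y x X` array.
#' @param reference `"mean"` (default) for the time-mean volume, or a
#'   1-based volume index.
#' @param mode `"rigid"` or `"none"` (identity, with an empty shift log).
#' @param max_shift shifts larger than this (pixels, either axis) are
#'   clamped to 0 as implausible (default a quarter of the slice).
#' @return list: `corrected` (same shape), `shifts` (data frame: volume,
#'   z, dy, dx).
#' @export
rigid_motion_correct <- function(hyperstack, reference = "mean",
                                 mode = c("rigid", "none"), max_shift = NULL) {
  mode <- match.arg(mode)
  d <- dim(hyperstack)
  if (mode == "none")
    return(list(corrected = hyperstack,
                shifts = data.frame(volume = integer(0), z = integer(0),
                                    dy = integer(0), dx = integer(0))))
  ref <- if (identical(reference, "mean")) {
    apply(hyperstack, c(2, 3, 4), mean)
  } else {
    hyperstack[reference, , , ]
  }
  max_shift <- max_shift %||% floor(min(d[3], d[4]) / 4)
  corrected <- hyperstack
  shifts <- vector("list", d[1] * d[2])
  k <- 0L
  ref_fft <- lapply(seq_len(d[2]), function(z) stats::fft(ref[z, , ] - mean(ref[z, , ])))
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      sl <- hyperstack[t, z, , ]
      k <- k + 1L
      if (stats::sd(sl) == 0) {
        warning(sprintf("constant slice (volume %d, z %d): zero shift", t, z))
        shifts[[k]] <- data.frame(volume = t, z = z, dy = 0L, dx = 0L)
        next
      }
      cp <- ref_fft[[z]] * Conj(stats::fft(sl - mean(sl)))
      cc <- Re(stats::fft(cp, inverse = TRUE))
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      s <- as.integer(pk - 1L)
      s <- ifelse(s > c(d[3], d[4]) / 2, s - c(d[3], d[4]), s)
      if (any(abs(s) > max_shift)) s <- c(0L, 0L)
      if (any(s != 0)) corrected[t, z, , ] <- circshift2(sl, s)
      shifts[[k]] <- data.frame(volume = t, z = z, dy = s[1], dx = s[2])
    }
  }
  list(corrected = corrected, shifts = do.call(rbind, shifts))
}
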