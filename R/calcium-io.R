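#' Write and read calcium sessions as multi-page TIFF
#'
#' One file per session; page order is volume-major then z (all z-slices
#' of volume 1, then volume 2, ...). Intensities are stored as 32-bit
#' float after division by a per-file scale (the maximum intensity),
#' which is recorded in a JSON sidecar (`<file>.json`) together with the
#' volume count and z-depth, so that reading restores the original
#' scale.
#'
#' @param session `T x Z x Y x X` array.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_calcium_tiff <- function(session, path) {
  d <- dim(session)
  stopifnot(length(d) == 4)
  scale <- max(session)
  if (scale <= 0) scale <- 1
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    k <- k + 1L
    pages[[k]] <- session[t, z, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(n_volumes = d[1], n_z = d[2], scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path TIFF path written by [write_calcium_tiff()].
#' @rdname write_calcium_tiff
#' @return for the reader: the restored `T x Z x Y x X` array.
#' @export
read_calcium_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_volumes * meta$n_z)
    stop("page count does not match the sidecar metadata")
  dy <- nrow(pages[[1]])
  dx <- ncol(pages[[1]])
  out <- array(NA_real_, c(meta$n_volumes, meta$n_z, dy, dx))
  k <- 0L
  for (t in seq_len(meta$n_volumes)) for (z in seq_len(meta$n_z)) {
    k <- k + 1L
    out[t, z, , ] <- pages[[k]] * meta$scale
  }
  out
}
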