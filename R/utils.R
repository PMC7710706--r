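`%||%` <- function(a, b) if (is.null(a)) b else a

rot2 <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Interior angle at a vertex, in degrees
#'
#' Angle in `[0, 180]` between the rays `vertex -> a` and `vertex -> b`.
#' Returns `NaN` if either ray has zero length.
#'
#' @param a,vertex,b numeric length-2 points.
#' @return angle in degrees.
#' @keywords internal
interior_angle <- function(a, vertex, b) {
  u <- a - vertex
  v <- b - vertex
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NaN)
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

# signed rotation (degrees, CCW positive) taking direction u to direction v
signed_turn <- function(u, v) {
  atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)) * 180 / pi
}

# distance from point p to the closed segment [a, b]
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab^2)
  if (denom == 0) return(sqrt(sum((p - a)^2)))
  t <- sum((p - a) * ab) / denom
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}

# remove runs shorter than min_len from a logical vector, shortest first;
# flipped runs merge with their neighbours
despeckle <- function(x, min_len = 3L) {
  if (min_len <= 1L || length(x) == 0L) return(x)
  repeat {
    r <- rle(x)
    if (length(r$lengths) <= 1L) return(x)
    short <- which(r$lengths < min_len)
    if (length(short) == 0L) return(x)
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    x[starts[i]:ends[i]] <- !r$values[i]
  }
}

# derive a per-entity seed from a master seed; keeps values in 32-bit range
derive_seed <- function(seed, entity_index, stream = 0L) {
  (as.integer(seed) %% 1000003L) * 1009L + entity_index * 131L + stream * 7919L
}
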