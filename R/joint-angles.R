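#' Compute leg joint angles from a pose series
#'
#' For one leg, returns the four interior joint angles per frame, in
#' degrees in `[0, 180]`: body-coxa (measured against the
#' posterior-pointing body axis defined by the `body_anterior` /
#' `body_posterior` landmarks), coxa-trochanter, femur-tibia, and
#' tibia-tarsus. Frames where any defining landmark has confidence below
#' `confidence_threshold`, or where adjacent landmarks coincide, are
#' `NaN`.
#'
#' @param pose a [pose_series()].
#' @param leg leg label (`"LF"`, ...).
#' @param confidence_threshold minimum landmark confidence (default 0.9).
#' @return matrix `frames x 4` with columns [JOINT_NAMES]; attribute
#'   `fps` carries the frame rate.
#' @export
compute_joint_angles <- function(pose, leg, confidence_threshold = 0.9) {
  lms <- leg_landmarks(leg)
  missing <- setdiff(c(lms, BODY_LANDMARKS), landmark_names(pose))
  if (length(missing) > 0)
    stop("pose series is missing landmarks: ", paste(missing, collapse = ", "))
  n <- n_frames(pose)
  P <- lapply(lms, function(nm) landmark_xy(pose, nm))
  ba <- landmark_xy(pose, "body_anterior")
  bp <- landmark_xy(pose, "body_posterior")
  conf <- pose$confidence[, lms, drop = FALSE]

  ang <- matrix(NaN, n, 4, dimnames = list(NULL, JOINT_NAMES))
  n_degenerate <- 0L
  for (k in seq_len(n)) {
    axis <- bp[k, ] - ba[k, ]
    # body-coxa: posterior body axis vs coxa, needs landmarks 1-2
    if (all(conf[k, 1:2] >= confidence_threshold) && any(axis != 0))
      ang[k, 1] <- interior_angle(P[[1]][k, ] + axis, P[[1]][k, ], P[[2]][k, ])
    for (j in 2:4) {
      if (all(conf[k, (j - 1):(j + 1)] >= confidence_threshold))
        ang[k, j] <- interior_angle(P[[j - 1]][k, ], P[[j]][k, ], P[[j + 1]][k, ])
    }
    if (anyNA(ang[k, ]) && all(conf[k, ] >= confidence_threshold))
      n_degenerate <- n_degenerate + 1L
  }
  if (n_degenerate > 0)
    message(sprintf("compute_joint_angles: %d frame(s) with coincident landmarks set to NaN",
                    n_degenerate))
  attr(ang, "fps") <- pose$fps
  attr(ang, "leg") <- leg
  ang
}
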