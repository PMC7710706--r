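#' Leg chain specification
#'
#' Describes one leg of the hexapod body plan: its identity, the 2-D
#' position of the body-coxa joint in the analysis frame (x positive
#' toward anterior, y up), and the four segment lengths.
#'
#' @param leg_id one of `"LF","LM","LH","RF","RM","RH"` (side then segment:
#'   L/R x F/M/H).
#' @param anchor numeric length-2, body-coxa position (mm).
#' @param segment_lengths named or unnamed numeric length-4: coxa, femur,
#'   tibia, tarsus lengths (mm), all positive.
#' @return an object of class `leg_chain`.
#' @export
leg_chain <- function(leg_id, anchor, segment_lengths) {
  stopifnot(length(anchor) == 2, length(segment_lengths) == 4)
  if (any(!is.finite(segment_lengths)) || any(segment_lengths <= 0))
    stop("all segment lengths must be positive")
  if (!leg_id %in% LEG_LABELS)
    stop("unknown leg_id: ", leg_id)
  structure(list(leg_id = leg_id, anchor = as.numeric(anchor),
                 segment_lengths = stats::setNames(as.numeric(segment_lengths),
                                                   c("coxa", "femur", "tibia", "tarsus"))),
            class = "leg_chain")
}

#' Leg labels and landmark naming
#'
#' Legs are labelled side-first (`L`/`R`) then segment (`F` fore, `M` mid,
#' `H` hind). Each leg carries five landmarks, proximal to distal.
#' @export
LEG_LABELS <- c("LF", "LM", "LH", "RF", "RM", "RH")

#' @rdname LEG_LABELS
#' @export
JOINT_NAMES <- c("body_coxa", "coxa_trochanter", "femur_tibia", "tibia_tarsus")

LANDMARK_SUFFIXES <- c("body_coxa", "coxa_trochanter", "femur_tibia",
                       "tibia_tarsus", "tarsal_tip")

#' @param leg leg label.
#' @rdname LEG_LABELS
#' @export
leg_landmarks <- function(leg) paste(leg, LANDMARK_SUFFIXES, sep = "_")

BODY_LANDMARKS <- c("body_anterior", "body_posterior")

#' Default hexapod body plan
#'
#' Six [leg_chain()] objects in a sagittal-projection analysis frame:
#' anchors at x = +1 (fore), 0 (mid), -1 (hind) mm, anchor height 2 mm
#' above the ground plane (y = 0), left and right legs sharing the same
#' projected geometry. Segment lengths approximate an adult Drosophila
#' leg (coxa 0.35, femur 0.8, tibia 0.9, tarsus 0.7 mm).
#'
#' @param anchor_height body-coxa height above ground (mm).
#' @return named list of `leg_chain` objects.
#' @export
body_plan <- function(anchor_height = 2.0) {
  seg <- c(coxa = 0.35, femur = 0.8, tibia = 0.9, tarsus = 0.7)
  ax <- c(F = 1.0, M = 0.0, H = -1.0)
  chains <- lapply(LEG_LABELS, function(id) {
    leg_chain(id, c(ax[[substr(id, 2, 2)]], anchor_height), seg)
  })
  stats::setNames(chains, LEG_LABELS)
}

#' Forward kinematics of a planar leg chain
#'
#' Places the five leg landmarks from four joint angles. The body-coxa
#' angle is measured between the posterior-pointing body axis and the
#' coxa; each subsequent angle is the interior angle between consecutive
#' segments. `bend` gives the turn direction at each joint (+1 =
#' counter-clockwise in the x-anterior/y-up frame); interior angles alone
#' do not determine a planar posture.
#'
#' @param chain a [leg_chain()].
#' @param angles numeric length-4, degrees in `[0, 180]` (body-coxa,
#'   coxa-trochanter, femur-tibia, tibia-tarsus).
#' @param bend numeric length-4 of +-1 turn signs.
#' @param axis unit vector of the posterior body direction (default
#'   `c(-1, 0)` in the anterior-positive frame).
#' @return a 5 x 2 matrix of landmark coordinates, proximal to distal.
#' @export
forward_kinematics <- function(chain, angles, bend = c(1, 1, 1, 1),
                               axis = c(-1, 0)) {
  stopifnot(inherits(chain, "leg_chain"), length(angles) == 4)
  if (any(!is.finite(angles)) || any(angles < 0 | angles > 180))
    stop("joint angles must lie in [0, 180] degrees")
  u <- unitv(axis)
  pts <- matrix(NA_real_, 5, 2)
  pts[1, ] <- chain$anchor
  d <- rot2(u, bend[1] * angles[1])
  pts[2, ] <- pts[1, ] + chain$segment_lengths[1] * d
  for (j in 2:4) {
    d <- rot2(d, bend[j] * (180 - angles[j]))
    pts[j + 1, ] <- pts[j, ] + chain$segment_lengths[j] * d
  }
  rownames(pts) <- LANDMARK_SUFFIXES
  pts
}

# angles (and turn signs) from a 5 x 2 landmark matrix; inverse of
# forward_kinematics up to the [0,180] angle convention
landmarks_to_angles <- function(pts, axis = c(-1, 0)) {
  u <- unitv(axis)
  a <- numeric(4)
  s <- numeric(4)
  d1 <- pts[2, ] - pts[1, ]
  a[1] <- interior_angle(pts[1, ] + u, pts[1, ], pts[2, ])
  s[1] <- sign(signed_turn(u, d1))
  for (j in 2:4) {
    a[j] <- interior_angle(pts[j - 1, ], pts[j, ], pts[j + 1, ])
    s[j] <- sign(signed_turn(pts[j, ] - pts[j - 1, ], pts[j + 1, ] - pts[j, ]))
  }
  s[s == 0] <- 1
  list(angles = a, bend = s)
}

# closed-form two-link placement: joint positions from p1 to p3 through an
# elbow with link lengths l1, l2; elbow_sign picks the solution branch
two_link_elbow <- function(p1, p3, l1, l2, elbow_sign = 1) {
  v <- p3 - p1
  r <- sqrt(sum(v^2))
  if (r > l1 + l2 + 1e-12 || r < abs(l1 - l2) - 1e-12)
    stop("two-link target out of reach: r = ", signif(r, 6))
  r <- min(max(r, abs(l1 - l2)), l1 + l2)
  cb <- (l1^2 + r^2 - l2^2) / (2 * l1 * r)
  beta <- acos(min(1, max(-1, cb))) * 180 / pi
  p1 + l1 * rot2(unitv(v), elbow_sign * beta)
}
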