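#' Gait generator parameters
#'
#' Parameters of the phase-coupled hexapod gait generator. Each leg's
#' tarsal tip cycles between an anterior extreme position (AEP) and a
#' posterior extreme position (PEP): during stance the tip travels along
#' the ground plane (from AEP to PEP when walking forward; reversed when
#' walking backward), during swing it returns along a half-ellipse whose
#' apex is `swing_height` above ground. `aep_x` and `pep_x` are offsets
#' (mm) from each leg's body-coxa anchor in the anterior-positive frame,
#' so `aep_x > pep_x`.
#'
#' @param step_frequency_hz step-cycle frequency (> 0).
#' @param duty_factor fraction of the cycle spent in stance, in (0, 1).
#' @param phase_offsets named numeric in `[0, 1)` per leg; the `"tripod"`
#'   preset couples \{LF, RM, LH\} at 0 and \{RF, LM, RH\} at 0.5.
#' @param direction `"forward"` or `"backward"`.
#' @param aep_x,pep_x stance extremes relative to the leg anchor (mm).
#' @param swing_height swing-arc apex height above ground (mm, >= 0).
#' @param landmark_noise_sd additive Gaussian noise on leg landmark
#'   coordinates (mm, >= 0).
#' @param seed master seed; per-leg streams are derived from it so adding
#'   legs does not perturb existing ones.
#' @return an object of class `gait_params`.
#' @export
gait_params <- function(step_frequency_hz = 2, duty_factor = 0.5,
                        phase_offsets = "tripod", direction = c("forward", "backward"),
                        aep_x = 0.4, pep_x = -0.4, swing_height = 0.2,
                        landmark_noise_sd = 0, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(step_frequency_hz > 0, duty_factor > 0, duty_factor < 1,
            swing_height >= 0, landmark_noise_sd >= 0)
  if (aep_x <= pep_x) stop("aep_x must exceed pep_x (anterior-positive frame)")
  if (identical(phase_offsets, "tripod"))
    phase_offsets <- c(LF = 0, RM = 0, LH = 0, RF = 0.5, LM = 0.5, RH = 0.5)
  if (is.null(names(phase_offsets)) || any(phase_offsets < 0 | phase_offsets >= 1))
    stop("phase_offsets must be a named vector with values in [0, 1)")
  structure(list(step_frequency_hz = step_frequency_hz, duty_factor = duty_factor,
                 phase_offsets = phase_offsets, direction = direction,
                 aep_x = aep_x, pep_x = pep_x, swing_height = swing_height,
                 landmark_noise_sd = landmark_noise_sd, seed = as.integer(seed)),
            class = "gait_params")
}

# tarsal-tip position for a vector of cycle phases in [0,1)
tip_path <- function(phase, params, anchor_x) {
  aep <- anchor_x + params$aep_x
  pep <- anchor_x + params$pep_x
  duty <- params$duty_factor
  stance <- phase < duty
  x <- numeric(length(phase))
  y <- numeric(length(phase))
  s <- phase[stance] / duty          # stance progress 0..1
  w <- (phase[!stance] - duty) / (1 - duty)  # swing progress 0..1
  if (params$direction == "forward") {
    x[stance] <- aep + (pep - aep) * s
    x[!stance] <- pep + (aep - pep) * w
  } else {
    x[stance] <- pep + (aep - pep) * s
    x[!stance] <- aep + (pep - aep) * w
  }
  y[!stance] <- params$swing_height * sin(pi * w)
  cbind(x = x, y = y)
}

#' Simulate a phase-coupled hexapod gait with known ground truth
#'
#' Generates a [pose_series()] for the full body plan together with the
#' true joint angles, the true swing mask, and the per-leg turn signs.
#' The tarsal-tip path is prescribed exactly (stance segment on the
#' ground plane from AEP to PEP, half-ellipse swing arc), and the
#' remaining joint positions follow from closed-form limb geometry: the
#' coxa hangs vertically from the anchor, the tarsus is vertical above
#' the tip, and the femur-tibia pair closes the gap as a two-link chain
#' (law of cosines). Ground-truth angles are the interior angles of that
#' posture, so forward kinematics of the stored angles reproduces the
#' noise-free landmarks exactly.
#'
#' @param params a [gait_params()].
#' @param chains named list of [leg_chain()] (default [body_plan()]).
#' @param duration_s recording length (s); must cover >= 2 full cycles.
#' @param fps frames per second (default 200, matching high-speed video).
#' @return a list of class `synthetic_pose_dataset` with elements `pose`,
#'   `true_angles` (per leg, frames x 4 matrices in degrees),
#'   `true_swing_mask` (a [footfall_pattern()]), `bend` (per-leg turn
#'   signs), `params`, and `chains`.
#' @export
simulate_gait <- function(params, chains = body_plan(), duration_s = 5,
                          fps = 200) {
  stopifnot(inherits(params, "gait_params"))
  if (fps <= 0 || duration_s <= 0) stop("fps and duration_s must be positive")
  if (duration_s * params$step_frequency_hz < 2)
    stop("duration must cover at least 2 full step cycles")
  legs <- names(chains)
  if (!all(legs %in% names(params$phase_offsets)))
    stop("phase_offsets missing for legs: ",
         paste(setdiff(legs, names(params$phase_offsets)), collapse = ", "))
  n <- as.integer(round(duration_s * fps))
  t_idx <- 0:(n - 1)

  lm_names <- c(BODY_LANDMARKS, unlist(lapply(legs, leg_landmarks)))
  coords <- array(NA_real_, c(n, length(lm_names), 2),
                  dimnames = list(NULL, lm_names, c("x", "y")))
  body_y <- chains[[1]]$anchor[2]
  coords[, "body_anterior", ] <- matrix(c(1.8, body_y), n, 2, byrow = TRUE)
  coords[, "body_posterior", ] <- matrix(c(-1.8, body_y), n, 2, byrow = TRUE)

  true_angles <- list()
  bend <- list()
  swing <- matrix(FALSE, length(legs), n, dimnames = list(legs, NULL))

  for (i in seq_along(legs)) {
    leg <- legs[i]
    ch <- chains[[leg]]
    phase <- (t_idx * params$step_frequency_hz / fps +
                params$phase_offsets[[leg]]) %% 1
    swing[leg, ] <- phase >= params$duty_factor
    tips <- tip_path(phase, params, ch$anchor[1])

    lens <- ch$segment_lengths
    p0 <- ch$anchor
    p1 <- p0 + c(0, -lens[["coxa"]])
    ang <- matrix(NA_real_, n, 4, dimnames = list(NULL, JOINT_NAMES))
    pts_all <- array(NA_real_, c(n, 5, 2))
    for (k in seq_len(n)) {
      p4 <- tips[k, ]
      p3 <- p4 + c(0, lens[["tarsus"]])
      p2 <- two_link_elbow(p1, p3, lens[["femur"]], lens[["tibia"]], elbow_sign = 1)
      pts <- rbind(p0, p1, p2, p3, p4)
      la <- landmarks_to_angles(pts)
      ang[k, ] <- la$angles
      if (k == 1) bend[[leg]] <- la$bend
      pts_all[k, , ] <- pts
    }
    true_angles[[leg]] <- ang

    if (params$landmark_noise_sd > 0) {
      set.seed(derive_seed(params$seed, i))
      pts_all <- pts_all +
        array(stats::rnorm(length(pts_all), 0, params$landmark_noise_sd),
              dim(pts_all))
    }
    coords[, leg_landmarks(leg), ] <- pts_all
  }

  structure(list(pose = pose_series(coords, fps = fps),
                 true_angles = true_angles,
                 true_swing_mask = footfall_pattern(swing, fps),
                 bend = bend, params = params, chains = chains),
            class = "synthetic_pose_dataset")
}
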