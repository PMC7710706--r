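#' Arena simulation parameters
#'
#' A cohort of flies walking in an open arena under an episode schedule:
#' responder flies walk backward (anti-parallel to heading) at
#' `backward_speed` during stimulus episodes and forward at
#' `forward_speed` otherwise; non-responders walk forward throughout.
#' Heading performs a Gaussian random walk.
#'
#' @param n_flies cohort size.
#' @param fps frame rate (default 30).
#' @param schedule an [episode_schedule()].
#' @param duration_s recording length (s); default covers the schedule
#'   plus one trailing second.
#' @param backward_speed episode backward speed for responders (mm/s,
#'   >= 0; default 4, comfortably above the 1.5 mm/s scoring threshold).
#' @param forward_speed inter-episode forward speed (mm/s, >= 0).
#' @param responder_fraction fraction of flies that respond, in `[0, 1]`.
#' @param heading_noise_sd per-frame heading increment SD (radians).
#' @param seed master seed; per-fly streams are derived from it.
#' @return an object of class `arena_sim_params`.
#' @export
arena_sim_params <- function(n_flies = 25, fps = 30,
                             schedule = episode_schedule(),
                             duration_s = NULL, backward_speed = 4,
                             forward_speed = 3, responder_fraction = 1,
                             heading_noise_sd = 0.05, seed = 1L) {
  stopifnot(n_flies >= 1, fps > 0, backward_speed >= 0, forward_speed >= 0,
            responder_fraction >= 0, responder_fraction <= 1,
            heading_noise_sd >= 0, inherits(schedule, "episode_schedule"))
  duration_s <- duration_s %||%
    (max(schedule$onsets_s + schedule$durations_s) + 1)
  if (duration_s < max(schedule$onsets_s + schedule$durations_s))
    stop("duration_s must cover the episode schedule")
  structure(list(n_flies = as.integer(n_flies), fps = fps, schedule = schedule,
                 duration_s = duration_s, backward_speed = backward_speed,
                 forward_speed = forward_speed,
                 responder_fraction = responder_fraction,
                 heading_noise_sd = heading_noise_sd, seed = as.integer(seed)),
            class = "arena_sim_params")
}

#' Simulate arena centroid tracks with known backward distances
#'
#' Integrates each fly's position frame by frame: the displacement over
#' `[t, t+1)` follows frame `t`'s heading at the signed speed set by the
#' schedule (negative = backward for responders during episodes). The
#' stored ground truth is each fly's total backward path length during
#' the episodes (`backward_speed x total episode time` for responders, 0
#' otherwise). Responders are the first `round(responder_fraction *
#' n_flies)` flies so the truth is deterministic given the parameters.
#'
#' @param params an [arena_sim_params()].
#' @return list of class `synthetic_arena_dataset`: `tracks` (list of
#'   [centroid_track()]), `truth` (data frame: fly_id, responder,
#'   backward_mm).
#' @export
simulate_arena <- function(params) {
  stopifnot(inherits(params, "arena_sim_params"))
  n <- as.integer(round(params$duration_s * params$fps))
  sched <- params$schedule
  t0 <- (0:(n - 1)) / params$fps
  in_episode <- rep(FALSE, n)
  for (i in seq_along(sched$onsets_s))
    in_episode <- in_episode | (t0 >= sched$onsets_s[i] &
                                  t0 < sched$onsets_s[i] + sched$durations_s[i])
  episode_time_s <- sum(in_episode) / params$fps

  n_resp <- round(params$responder_fraction * params$n_flies)
  tracks <- vector("list", params$n_flies)
  truth <- data.frame(fly_id = character(params$n_flies),
                      responder = logical(params$n_flies),
                      backward_mm = numeric(params$n_flies),
                      stringsAsFactors = FALSE)
  for (f in seq_len(params$n_flies)) {
    responder <- f <= n_resp
    set.seed(derive_seed(params$seed, f, stream = 2L))
    heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                        stats::rnorm(n - 1, 0, params$heading_noise_sd)))
    speed <- rep(params$forward_speed, n)
    if (responder) speed[in_episode] <- -params$backward_speed
    dt <- 1 / params$fps
    x <- cumsum(c(0, speed[-n] * cos(heading[-n]) * dt))
    y <- cumsum(c(0, speed[-n] * sin(heading[-n]) * dt))
    id <- sprintf("fly%02d", f)
    tracks[[f]] <- centroid_track(x, y, heading, fps = params$fps, fly_id = id)
    truth$fly_id[f] <- id
    truth$responder[f] <- responder
    truth$backward_mm[f] <- if (responder)
      params$backward_speed * episode_time_s else 0
  }
  structure(list(tracks = tracks, truth = truth, params = params),
            class = "synthetic_arena_dataset")
}
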