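#' Optogenetic stimulus protocol for a calcium imaging session
#'
#' One imaging session is `session_volumes` volumes at `volume_rate`
#' volumes/s; red-light stimulus epochs are given as onset/duration
#' pairs in seconds from imaging start. Each epoch is a train of short
#' pulses (`pulse_width_s` at `pulse_rate_hz`), which sets the light
#' duty cycle. Presets match the two standard protocols: one 20-s
#' stimulus at 10 s, or two 1-s stimuli at 10 s and 40 s.
#'
#' @param preset `"20s"`, `"1s"`, or `NULL` to give `epochs` directly.
#' @param session_volumes volumes per session (default 60).
#' @param volume_rate volumes per second (default 1).
#' @param epochs data frame with columns `onset_s`, `duration_s`.
#' @param pulse_width_s pulse width (s, default 0.005).
#' @param pulse_rate_hz pulse rate (Hz, default 50).
#' @param source_power_mw time-averaged light power at the sample (mW,
#'   default 0.81).
#' @param fov_diameter_mm illuminated field-of-view diameter (mm,
#'   default 0.9).
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(preset = c("20s", "1s"), session_volumes = 60L,
                              volume_rate = 1, epochs = NULL,
                              pulse_width_s = 0.005, pulse_rate_hz = 50,
                              source_power_mw = 0.81, fov_diameter_mm = 0.9) {
  if (is.null(epochs)) {
    preset <- match.arg(preset)
    epochs <- switch(preset,
                     "20s" = data.frame(onset_s = 10, duration_s = 20),
                     "1s" = data.frame(onset_s = c(10, 40), duration_s = c(1, 1)))
  } else {
    preset <- "custom"
    stopifnot(all(c("onset_s", "duration_s") %in% names(epochs)))
  }
  session_s <- session_volumes / volume_rate
  if (any(epochs$onset_s < 0 | epochs$onset_s + epochs$duration_s > session_s))
    stop("stimulus epochs must lie within the session")
  if (pulse_width_s * pulse_rate_hz > 1)
    stop("pulse width x pulse rate must not exceed 1")
  structure(list(preset = preset, session_volumes = as.integer(session_volumes),
                 volume_rate = volume_rate, epochs = epochs,
                 pulse_width_s = pulse_width_s, pulse_rate_hz = pulse_rate_hz,
                 source_power_mw = source_power_mw,
                 fov_diameter_mm = fov_diameter_mm),
            class = "stimulus_protocol")
}

#' Stimulus protocol summary: duty cycle, light intensity, epoch table
#'
#' The pulse-train duty cycle is `pulse_width_s * pulse_rate_hz`; the
#' light intensity spreads the source power over the circular field of
#' view, `power / (pi * (diameter/2)^2)` in mW/mm^2.
#'
#' @param protocol a [stimulus_protocol()].
#' @return list with `duty_cycle`, `intensity_mw_mm2`, `epochs`.
#' @export
protocol_summary <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (protocol$fov_diameter_mm <= 0) stop("field-of-view diameter must be positive")
  list(duty_cycle = protocol$pulse_width_s * protocol$pulse_rate_hz,
       intensity_mw_mm2 = protocol$source_power_mw /
         (pi * (protocol$fov_diameter_mm / 2)^2),
       epochs = protocol$epochs)
}

# stimulus boxcar sampled at the volume rate: 1 where the volume's
# acquisition time falls inside an epoch
stimulus_boxcar <- function(protocol) {
  tt <- (seq_len(protocol$session_volumes) - 1) / protocol$volume_rate
  on <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(protocol$epochs)))
    on <- on | (tt >= protocol$epochs$onset_s[i] &
                  tt < protocol$epochs$onset_s[i] + protocol$epochs$duration_s[i])
  as.numeric(on)
}

#' Synthesize a GCaMP response kernel for a stimulus protocol
#'
#' The stimulus boxcar (sampled at the volume rate) is convolved with a
#' normalized difference-of-exponentials impulse response,
#' `exp(-t/tau_decay) - exp(-t/tau_rise)`, and the result is scaled to a
#' peak of 1. The kernel has one sample per volume of the session. Time
#' constants default to slow-indicator (GCaMP6s-like) dynamics.
#'
#' @param protocol a [stimulus_protocol()].
#' @param tau_rise_s,tau_decay_s indicator time constants (s),
#'   `0 < tau_rise_s < tau_decay_s`.
#' @return an object of class `response_kernel`: `trace` (length =
#'   session volumes; peak 1, or all zero for an empty stimulus),
#'   `protocol_tag`, `volume_rate`.
#' @export
make_gcamp_kernel <- function(protocol, tau_rise_s = 0.2, tau_decay_s = 1.5) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (tau_rise_s <= 0 || tau_decay_s <= tau_rise_s)
    stop("need 0 < tau_rise_s < tau_decay_s")
  box <- stimulus_boxcar(protocol)
  n <- length(box)
  tt <- (0:(n - 1)) / protocol$volume_rate
  h <- exp(-tt / tau_decay_s) - exp(-tt / tau_rise_s)
  k <- numeric(n)
  for (t in seq_len(n))  # causal discrete convolution, truncated at session end
    k[t] <- sum(box[seq_len(t)] * h[t - seq_len(t) + 1])
  pk <- max(k)
  if (pk > 0) k <- k / pk
  structure(list(trace = k, protocol_tag = protocol$preset,
                 volume_rate = protocol$volume_rate),
            class = "response_kernel")
}
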