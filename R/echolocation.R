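# Generative model of Myotis attack call sequences: phase schedule, pulse
# intervals, the localization intensity ramp, and automatic gain control.

PHASES <- c("search", "approach", "buzz")

#' Classify echolocation phase from pulse interval
#'
#' Phase boundaries are induced from the representative pulse intervals of
#' each phase (search: 80 and 100 ms; approach: 20, 30 and 45 ms; buzz: 4
#' and 7 ms) with 12 and 60 ms treated as transitional: pulse intervals at
#' or below `buzz_max_ms` are buzz, above `approach_max_ms` are search,
#' and approach in between.
#'
#' @param pulse_interval_ms start-to-start pulse interval(s), ms (> 0).
#' @param buzz_max_ms upper buzz boundary (default 10 ms).
#' @param approach_max_ms upper approach boundary (default 60 ms).
#' @return factor with levels search, approach, buzz.
#' @export
classify_phase <- function(pulse_interval_ms, buzz_max_ms = 10,
                           approach_max_ms = 60) {
  if (any(!is.finite(pulse_interval_ms)) || any(pulse_interval_ms <= 0))
    stop("pulse_interval_ms must be positive")
  out <- ifelse(pulse_interval_ms <= buzz_max_ms, "buzz",
                ifelse(pulse_interval_ms <= approach_max_ms,
                       "approach", "search"))
  factor(out, levels = PHASES)
}

#' Echolocation sequence parameters
#'
#' Conditions of a Myotis attack sequence: search-phase emission rate
#' 7--12 calls/s, terminal buzz near 160 calls/s, approach-phase pulse
#' intervals shrinking from 60 to 20 ms, and automatic gain control
#' holding the level at the target near a constant setpoint (field
#' estimate 95.3 dB peSPL during gain control).
#'
#' @param search_rate search-phase call rate, calls/s within \[7, 12\].
#' @param buzz_rate terminal-buzz call rate, calls/s.
#' @param approach_pi_start_ms,approach_pi_end_ms approach-phase pulse
#'   interval schedule endpoints (ms, decreasing).
#' @param gain_control_setpoint_dB level held at the target once gain
#'   control engages (dB peSPL).
#' @param search_source_level_dB on-axis source level during search.
#' @param detection_distance_m bat-to-prey distance at detection (m).
#' @param localization_duration_s duration of the post-detection
#'   localization intensity ramp (s).
#' @param buzz_duration_s duration of the terminal buzz before capture.
#' @param pi_jitter_sd lognormal sigma of multiplicative pulse-interval
#'   jitter (0 disables).
#' @param frequency_kHz call peak frequency (kHz).
#' @param duration_ms call duration (ms).
#' @return an object of class `sequence_params`.
#' @export
sequence_params <- function(search_rate = 10, buzz_rate = 160,
                            approach_pi_start_ms = 60,
                            approach_pi_end_ms = 20,
                            gain_control_setpoint_dB = 95.3,
                            search_source_level_dB = 110,
                            detection_distance_m = 3,
                            localization_duration_s = 0.2,
                            buzz_duration_s = 0.3,
                            pi_jitter_sd = 0.05,
                            frequency_kHz = 40, duration_ms = 2) {
  stopifnot(search_rate > 0, buzz_rate > 0,
            approach_pi_start_ms > approach_pi_end_ms,
            approach_pi_end_ms > 0,
            detection_distance_m > 0, localization_duration_s >= 0,
            buzz_duration_s >= 0, pi_jitter_sd >= 0)
  if (search_rate < 7 || search_rate > 12)
    warning("search_rate outside the typical 7-12 calls/s range")
  structure(as.list(environment()), class = "sequence_params")
}

#' Source level under automatic gain control
#'
#' Emission level that holds the received level at the target exactly at
#' the setpoint in the noise-free forward model:
#' `SL = setpoint + transmission_loss(distance)`.
#'
#' @param distance_m bat-to-target distance (m, >= 0.1).
#' @param setpoint_dB target received level (dB peSPL).
#' @param frequency_kHz call frequency.
#' @param env a [environment_conditions()] object.
#' @return on-axis source level at 10 cm, dB peSPL.
#' @export
gain_control_source_level <- function(distance_m, setpoint_dB = 95.3,
                                      frequency_kHz = 40,
                                      env = environment_conditions()) {
  setpoint_dB + transmission_loss(distance_m, frequency_kHz, env)
}

#' Generate an attack call sequence
#'
#' Builds the call-level record of a Myotis attack along a supplied
#' bat-target distance timeline: search-phase calls until the target
#' comes within the detection distance; an approach phase whose pulse
#' interval shrinks linearly (in emission time) from the schedule start
#' to its end while the source level ramps up during localization and
#' then follows automatic gain control; and a terminal buzz at the buzz
#' rate over the final `buzz_duration_s`. The beam off-axis angle
#' converges linearly from `beam_initial_offaxis_deg` at detection to
#' under 3 degrees by late approach (sonar "lock").
#'
#' @param params a [sequence_params()].
#' @param distance_fn function(t) giving bat-target distance (m) at time
#'   t (s); must be defined over \[0, t_end\].
#' @param t_end end of the attack (capture time), seconds.
#' @param env a [environment_conditions()] object.
#' @param beam_initial_offaxis_deg beam-to-target angle at the start.
#' @param seed integer seed for the pulse-interval jitter (`NULL` leaves
#'   the RNG state alone).
#' @return data frame of class `call_sequence`: one row per call with
#'   emission time, pulse interval, frequency, duration, on-axis source
#'   level, beam off-axis angle to the target, and phase label.
#' @export
generate_call_sequence <- function(params, distance_fn, t_end,
                                   env = environment_conditions(),
                                   beam_initial_offaxis_deg = 30,
                                   seed = NULL) {
  stopifnot(inherits(params, "sequence_params"), is.function(distance_fn),
            t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  jit <- function(n) if (params$pi_jitter_sd > 0)
    stats::rlnorm(n, -params$pi_jitter_sd^2 / 2, params$pi_jitter_sd) else
      rep(1, n)

  # detection time: first time distance <= detection_distance
  dgrid <- seq(0, t_end, length.out = 2048L)
  dd <- vapply(dgrid, distance_fn, numeric(1))
  det_idx <- which(dd <= params$detection_distance_m)
  if (!length(det_idx))
    stop("timeline never enters the detection distance; no approach phase possible")
  t_detect <- dgrid[min(det_idx)]
  t_buzz <- max(t_end - params$buzz_duration_s, t_detect)
  if (t_detect <= 0)
    stop("timeline too short: no search phase before detection")
  if (t_buzz <= t_detect)
    stop("timeline too short: approach phase has zero duration")

  # search phase: constant rate until detection
  pi_search_s <- 1 / params$search_rate
  times <- c(); t <- 0
  while (t < t_detect) { times <- c(times, t); t <- t + pi_search_s * jit(1) }
  n_search <- length(times)

  # approach: PI decreasing linearly with time across [t_detect, t_buzz]
  t <- if (n_search) max(times[n_search] + pi_search_s, t_detect) else t_detect
  pi_at <- function(tt) {
    frac <- (tt - t_detect) / (t_buzz - t_detect)
    (params$approach_pi_start_ms +
        frac * (params$approach_pi_end_ms - params$approach_pi_start_ms)) / 1000
  }
  while (t < t_buzz) { times <- c(times, t); t <- t + pi_at(t) * jit(1) }

  # terminal buzz
  pi_buzz_s <- 1 / params$buzz_rate
  t <- max(t, t_buzz)
  while (t <= t_end) { times <- c(times, t); t <- t + pi_buzz_s * jit(1) }
  n <- length(times)

  dist <- vapply(times, function(tt) max(distance_fn(tt), REF_DISTANCE_M),
                 numeric(1))
  phase <- ifelse(times < t_detect, "search",
                  ifelse(times < t_buzz, "approach", "buzz"))

  # source level: search level, then linear localization ramp up to the
  # gain-control level at ramp end, then gain control (SL falls with d)
  t_lock <- min(t_detect + params$localization_duration_s, t_buzz)
  sl <- numeric(n)
  sl_peak <- gain_control_source_level(
    max(vapply(times[times >= t_lock], function(tt)
      max(distance_fn(tt), REF_DISTANCE_M), numeric(1)), REF_DISTANCE_M),
    params$gain_control_setpoint_dB, params$frequency_kHz, env)
  for (i in seq_len(n)) {
    tt <- times[i]
    if (tt < t_detect) {
      sl[i] <- params$search_source_level_dB
    } else if (tt < t_lock) {
      frac <- (tt - t_detect) / (t_lock - t_detect)
      sl[i] <- params$search_source_level_dB +
        frac * (sl_peak - params$search_source_level_dB)
    } else {
      sl[i] <- gain_control_source_level(dist[i],
                                         params$gain_control_setpoint_dB,
                                         params$frequency_kHz, env)
    }
  }

  # beam-to-target angle: wide during search, converging to < 3 deg by
  # the time the localization ramp completes (sonar lock)
  offax <- numeric(n)
  for (i in seq_len(n)) {
    tt <- times[i]
    if (tt < t_detect) offax[i] <- beam_initial_offaxis_deg
    else if (tt < t_lock)
      offax[i] <- beam_initial_offaxis_deg *
        (1 - (tt - t_detect) / (t_lock - t_detect))
    else offax[i] <- 0
  }

  pi_ms <- c(NA_real_, diff(times)) * 1000
  out <- data.frame(time_s = times, pulse_interval_ms = pi_ms,
                    freq_khz = params$frequency_kHz,
                    duration_ms = params$duration_ms,
                    source_level_db = sl,
                    beam_offaxis_deg = offax,
                    phase = factor(phase, levels = PHASES),
                    stringsAsFactors = FALSE)
  attr(out, "t_detect") <- t_detect
  attr(out, "t_lock") <- t_lock
  attr(out, "t_buzz") <- t_buzz
  class(out) <- c("call_sequence", "data.frame")
  out
}
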