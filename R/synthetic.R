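# Seeded synthetic scenarios: real-threat attacks (bat converges on the
# focal moth), false-threat attacks (bat attacks a free-flying neighbor),
# non-attack passes, and laboratory ramp playbacks with a simulated
# clicking moth. Every downstream stage is testable without field data.

#' Attack-scenario generation parameters
#'
#' Defaults reproduce the study conditions: detection distances drawn
#' within 2.2--4.5 m, bat flight speeds 2--6 m/s, the microphone tethered
#' within 0.5 m of the focal moth, and neighbors (false threats) placed
#' 0.7--2 m from the focal moth.
#'
#' @param detection_range_m range the detection distance is drawn from.
#' @param speed_range_m_s range of bat flight speeds.
#' @param neighbor_range_m range of focal-to-neighbor distances (false
#'   threats).
#' @param mic_offset_m microphone distance below the focal moth (m,
#'   < 0.5 per the tether geometry).
#' @param start_distance_m bat starting distance from its target.
#' @param capture_distance_m bat-target distance at the end of an attack.
#' @param pass_miss_distance_m closest approach for non-attack passes.
#' @param env a [environment_conditions()] object.
#' @param seq_params a [sequence_params()] object (detection distance is
#'   overridden per scenario by the seeded draw).
#' @return an object of class `scenario_params`.
#' @export
scenario_params <- function(detection_range_m = c(2.2, 4.5),
                            speed_range_m_s = c(2, 6),
                            neighbor_range_m = c(0.7, 2),
                            mic_offset_m = 0.3,
                            start_distance_m = 8,
                            capture_distance_m = 0.1,
                            pass_miss_distance_m = 3,
                            env = environment_conditions(),
                            seq_params = sequence_params()) {
  stopifnot(mic_offset_m < 0.5, all(detection_range_m > 0),
            all(speed_range_m_s > 0), start_distance_m > max(detection_range_m),
            capture_distance_m >= REF_DISTANCE_M)
  structure(as.list(environment()), class = "scenario_params")
}

# unit vector helper
.unit <- function(v) v / sqrt(sum(v^2))

#' Generate a complete attack scenario
#'
#' Builds bat track, moth/microphone geometry and the echolocation call
#' sequence for one encounter. `"real"`: the bat flies a straight
#' constant-speed path onto the focal moth. `"false"`: the bat attacks a
#' free-flying neighbor 0.7--2 m away, approaching from the hemisphere
#' away from the focal moth so the focal moth is never the target.
#' `"pass"`: the bat transits the area in search phase without attacking.
#' Deterministic for a fixed seed.
#'
#' @param threat_type one of `"real"`, `"false"`, `"pass"`.
#' @param params a [scenario_params()].
#' @param seed integer seed.
#' @return an object of class `attack_scenario`: list with `threat_type`,
#'   `bat_track` ([raw_track()]), `focal_moth`, `neighbor_moth` (or NULL),
#'   `target`, `mic` ([microphone_model()]), `env`, `calls`
#'   (a `call_sequence`), `capture_time_s`, `seed`.
#' @export
make_attack_scenario <- function(threat_type = c("real", "false", "pass"),
                                 params = scenario_params(), seed = 1L) {
  threat_type <- match.arg(threat_type)
  stopifnot(inherits(params, "scenario_params"))
  set.seed(seed)

  focal <- c(0, 0, 5)  # tethered moth hoisted on the pole
  neighbor <- NULL
  if (threat_type == "false") {
    # neighbor displaced horizontally from the focal moth
    az <- stats::runif(1, 0, 2 * pi)
    rn <- stats::runif(1, params$neighbor_range_m[1],
                       params$neighbor_range_m[2])
    neighbor <- focal + rn * c(cos(az), sin(az), 0)
  }
  target <- switch(threat_type, real = focal, false = neighbor,
                   pass = NULL)

  speed <- stats::runif(1, params$speed_range_m_s[1],
                        params$speed_range_m_s[2])
  det <- stats::runif(1, params$detection_range_m[1],
                      params$detection_range_m[2])
  sp <- params$seq_params
  sp$detection_distance_m <- det

  if (threat_type == "pass") {
    # straight transit with closest approach pass_miss_distance_m
    az <- stats::runif(1, 0, 2 * pi)
    dir <- c(cos(az), sin(az), 0)
    perp <- c(-sin(az), cos(az), 0)
    closest <- focal + params$pass_miss_distance_m * perp
    half <- params$start_distance_m
    t_end <- 2 * half / speed
    fps_times <- unique(c(seq(0, t_end, by = 1 / 60), t_end))
    pos <- t(vapply(fps_times,
                    function(tt) closest + (speed * tt - half) * dir,
                    numeric(3)))
    # search-phase-only sequence at the search rate over the transit
    pi_s <- 1 / sp$search_rate
    times <- seq(0, t_end, by = pi_s)
    calls <- data.frame(time_s = times,
                        pulse_interval_ms = c(NA_real_, diff(times)) * 1000,
                        freq_khz = sp$frequency_kHz,
                        duration_ms = sp$duration_ms,
                        source_level_db = sp$search_source_level_dB,
                        beam_offaxis_deg = 30,
                        phase = factor("search", levels = PHASES))
    class(calls) <- c("call_sequence", "data.frame")
  } else {
    # approach direction: for false threats, from the hemisphere away
    # from the focal moth so the final bat-focal distance exceeds the
    # focal-neighbor separation
    repeat {
      u <- .unit(stats::rnorm(3) * c(1, 1, 0.3))
      if (threat_type == "real") break
      if (sum(u * (focal - target)) < -0.1) break
    }
    start <- target + params$start_distance_m * u
    dist0 <- params$start_distance_m
    t_end <- (dist0 - params$capture_distance_m) / speed
    fps_times <- unique(c(seq(0, t_end, by = 1 / 60), t_end))
    pos <- t(vapply(fps_times,
                    function(tt) start - speed * tt * u, numeric(3)))
    distance_fn <- function(tt) dist0 - speed * tt
    calls <- generate_call_sequence(sp, distance_fn, t_end,
                                    env = params$env, seed = seed + 1L)
  }

  bat_track <- raw_track(fps_times, pos)
  mic_pos <- focal - c(0, 0, params$mic_offset_m)
  mic <- default_microphone(position = mic_pos,
                            axis = c(0, 0, 1))  # pointing up the pole
  structure(list(threat_type = threat_type, bat_track = bat_track,
                 focal_moth = focal, neighbor_moth = neighbor,
                 target = if (is.null(target)) focal else target,
                 mic = mic, env = params$env, calls = calls,
                 capture_time_s = t_end, params = params, seed = seed),
            class = "attack_scenario")
}

#' @export
print.attack_scenario <- function(x, ...) {
  cat(sprintf("<attack_scenario> %s threat: %d calls over %.2f s (seed %d)\n",
              x$threat_type, nrow(x$calls), x$capture_time_s, x$seed))
  invisible(x)
}

# linear interpolation of the raw bat track at call times
.bat_position_at <- function(scn, t) {
  tr <- scn$bat_track
  out <- vapply(1:3, function(j)
    stats::approx(tr$times, tr$positions[, j], xout = t, rule = 2)$y,
    numeric(length(t)))
  if (length(t) == 1L) matrix(out, 1L, 3L) else out
}

#' Forward-simulate received levels for a scenario
#'
#' The forward counterpart of the calibration chain: for every call,
#' the level at the microphone and at the focal moth is the on-axis
#' source level plus the beam directivity gain toward that receiver
#' minus the one-way transmission loss. The recorded level additionally
#' passes through the microphone's frequency response and
#' directionality. Optional Gaussian measurement noise (dB) is added to
#' the recorded level last, seeded.
#'
#' With `idealized = TRUE` the beam gain toward the microphone is set to
#' exactly 3 dB below the gain toward the moth, matching the fixed +3 dB
#' compensation the calibration inverse applies; the inverse then
#' recovers source level and level-at-moth exactly (round-trip oracle).
#'
#' @param scn an [make_attack_scenario()] scenario.
#' @param noise_sd_dB standard deviation of recorded-level noise.
#' @param idealized logical; see Details.
#' @param seed seed for the noise draw.
#' @return data frame of class `received_levels`: per call, the true
#'   geometry (distances, angles), true levels at mic and moth, and the
#'   recorded (sensor) level.
#' @export
simulate_received_levels <- function(scn, noise_sd_dB = 0,
                                     idealized = FALSE, seed = 1L) {
  stopifnot(inherits(scn, "attack_scenario"))
  calls <- scn$calls
  tmax <- max(scn$bat_track$times)
  ok <- calls$time_s <= tmax + 1e-9
  if (any(!ok))
    warning(sprintf("%d call(s) outside the track time range excluded",
                    sum(!ok)))
  calls <- calls[ok, , drop = FALSE]
  bat <- .bat_position_at(scn, calls$time_s)
  moth <- scn$focal_moth
  micp <- scn$mic$position

  to_moth <- sweep(-bat, 2, -moth)      # moth - bat
  to_mic <- sweep(-bat, 2, -micp)
  d_moth <- pmax(sqrt(rowSums(to_moth^2)), REF_DISTANCE_M)
  d_mic <- pmax(sqrt(rowSums(to_mic^2)), REF_DISTANCE_M)

  angle_between <- function(A, B) {
    cosv <- rowSums(A * B) / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2)))
    acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
  }
  # beam axis: unit vector toward the bat's own target, rotated off by
  # the call's beam_offaxis_deg within the vertical plane of approach
  to_target <- sweep(-bat, 2, -scn$target)
  beam_axes <- t(vapply(seq_len(nrow(bat)), function(i) {
    axis0 <- .unit(to_target[i, ])
    th <- calls$beam_offaxis_deg[i] * pi / 180
    # rotate within the plane spanned by axis0 and a fixed perpendicular
    ref <- if (abs(axis0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    perp <- .unit(ref - sum(ref * axis0) * axis0)
    cos(th) * axis0 + sin(th) * perp
  }, numeric(3)))

  ang_beam_moth <- angle_between(beam_axes, to_moth)
  ang_beam_mic <- angle_between(beam_axes, to_mic)
  ang_bm_bm <- angle_between(to_moth, to_mic)  # bat-moth vs bat-mic
  # incidence on the mic relative to its axis (sound arrives from the bat)
  mic_offax <- angle_between(-to_mic,
                             matrix(scn$mic$axis, nrow(bat), 3, byrow = TRUE))

  phase_chr <- as.character(calls$phase)
  tl_moth <- transmission_loss(d_moth, calls$freq_khz[1], scn$env)
  tl_mic <- transmission_loss(d_mic, calls$freq_khz[1], scn$env)
  g_moth <- vapply(seq_along(phase_chr), function(i)
    beam_gain(ang_beam_moth[i], phase_chr[i]), numeric(1))
  g_mic <- if (idealized) g_moth - 3 else
    vapply(seq_along(phase_chr), function(i)
      beam_gain(ang_beam_mic[i], phase_chr[i]), numeric(1))

  spl_moth <- calls$source_level_db + g_moth - tl_moth
  spl_mic <- calls$source_level_db + g_mic - tl_mic
  micc <- mic_correction(calls$freq_khz, mic_offax, scn$mic)
  recorded <- spl_mic - micc
  if (noise_sd_dB > 0) {
    set.seed(seed)
    recorded <- recorded + stats::rnorm(length(recorded), 0, noise_sd_dB)
  }

  out <- data.frame(time_s = calls$time_s,
                    pulse_interval_ms = calls$pulse_interval_ms,
                    freq_khz = calls$freq_khz,
                    phase = calls$phase,
                    source_level_db = calls$source_level_db,
                    d_bat_moth_m = d_moth, d_bat_mic_m = d_mic,
                    angle_batmoth_batmic_deg = ang_bm_bm,
                    mic_offaxis_deg = mic_offax,
                    beam_gain_moth_db = g_moth, beam_gain_mic_db = g_mic,
                    true_spl_at_moth_db = spl_moth,
                    true_spl_at_mic_db = spl_mic,
                    recorded_level_db = recorded)
  class(out) <- c("received_levels", "data.frame")
  out
}

RAMP_PULSE_INTERVALS_MS <- c(4, 7, 12, 20, 30, 45, 60, 80, 100)

#' Laboratory ramp playback stimulus
#'
#' A 10 s train of 2 ms, 40 kHz pulses (0.5 ms rise/fall) at a fixed
#' pulse interval whose level at the moth rises at 5 dB/s from 70 to
#' 120 dB SPL: pulse k at time `t_k = k * PI` has level `70 + 5 t_k`.
#'
#' @param pulse_interval_ms one of 4, 7, 12, 20, 30, 45, 60, 80, 100 ms.
#' @return an object of class `ramp_stimulus` with `pulse_times_s` and
#'   `pulse_levels_db`.
#' @export
make_ramp_playback <- function(pulse_interval_ms) {
  if (length(pulse_interval_ms) != 1L ||
      !pulse_interval_ms %in% RAMP_PULSE_INTERVALS_MS)
    stop("pulse_interval_ms must be one of: ",
         paste(RAMP_PULSE_INTERVALS_MS, collapse = ", "), " ms")
  times <- seq(0, 10 - 1e-9, by = pulse_interval_ms / 1000)
  structure(list(pulse_interval_ms = pulse_interval_ms,
                 duration_s = 10, rate_db_per_s = 5, start_db = 70,
                 frequency_kHz = 40, pulse_duration_ms = 2,
                 rise_fall_ms = 0.5,
                 pulse_times_s = times,
                 pulse_levels_db = 70 + 5 * times),
            class = "ramp_stimulus")
}

#' Simulated clicking-moth response model
#'
#' @param threshold_curve a [threshold_curve()] mapping pulse interval to
#'   clicking threshold (dB).
#' @param latency_ms response latency added to the click time (default 0
#'   for determinism).
#' @param noise_sd_dB per-trial Gaussian jitter of the threshold.
#' @return an object of class `moth_response_model`.
#' @export
moth_response_model <- function(threshold_curve, latency_ms = 0,
                                noise_sd_dB = 0) {
  stopifnot(inherits(threshold_curve, "threshold_curve"),
            latency_ms >= 0, noise_sd_dB >= 0)
  structure(list(threshold_curve = threshold_curve,
                 latency_ms = latency_ms, noise_sd_dB = noise_sd_dB),
            class = "moth_response_model")
}

#' Simulate a moth's clicking response
#'
#' The moth clicks at the first pulse (ramp playback) or call (attack
#' scenario) whose level at the moth meets or exceeds its threshold at
#' that pulse interval, plus its response latency. With threshold noise,
#' one seeded threshold draw is made per trial. Returns `NA` if the
#' threshold is never exceeded.
#'
#' @param x a `ramp_stimulus` or the `received_levels` of a scenario.
#' @param moth a [moth_response_model()].
#' @param seed seed for the threshold-noise draw.
#' @return the first click time in seconds, or `NA_real_`.
#' @export
simulate_moth_response <- function(x, moth, seed = 1L) {
  stopifnot(inherits(moth, "moth_response_model"))
  if (moth$noise_sd_dB > 0) set.seed(seed)
  dthr <- if (moth$noise_sd_dB > 0)
    stats::rnorm(1, 0, moth$noise_sd_dB) else 0
  if (inherits(x, "ramp_stimulus")) {
    thr <- threshold_at(moth$threshold_curve, x$pulse_interval_ms) + dthr
    hit <- which(x$pulse_levels_db >= thr)
    if (!length(hit)) return(NA_real_)
    x$pulse_times_s[min(hit)] + moth$latency_ms / 1000
  } else if (inherits(x, "received_levels")) {
    pi_ms <- x$pulse_interval_ms
    lev <- x$true_spl_at_moth_db
    ok <- which(!is.na(pi_ms) &
                  lev >= threshold_at(moth$threshold_curve, pi_ms) + dthr)
    if (!length(ok)) return(NA_real_)
    x$time_s[min(ok)] + moth$latency_ms / 1000
  } else stop("x must be a ramp_stimulus or received_levels")
}
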