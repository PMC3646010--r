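# The audio-calibration inverse: from recorded microphone levels plus 3-D
# geometry, estimate each call's source level at 10 cm (in the moth's
# direction) and its level at the moth; then per-event intensity/PI
# features and attack-aligned trends.

#' Sound pressure level at the microphone from a recorded level
#'
#' Adds the microphone's frequency-response and directionality correction
#' to the raw recorded level to obtain the true SPL at the microphone.
#'
#' @param recorded_level_dB raw level through the recording chain.
#' @param frequency_kHz call peak frequency.
#' @param mic_offaxis_deg incidence angle off the microphone axis.
#' @param mic a [microphone_model()].
#' @return SPL at the microphone, dB.
#' @export
estimate_spl_at_mic <- function(recorded_level_dB, frequency_kHz,
                                mic_offaxis_deg, mic = default_microphone()) {
  recorded_level_dB + mic_correction(frequency_kHz, mic_offaxis_deg, mic)
}

#' Source level at 10 cm in the moth's direction
#'
#' Back-propagates the SPL at the microphone to the 10 cm reference
#' distance and adds a fixed +3 dB compensation for the beam-direction
#' difference between the bat-microphone and bat-moth vectors (the
#' microphone sits slightly off the moth, hence slightly further off the
#' sonar beam). The result is the emission level in the moth's direction,
#' not necessarily the bat's on-axis maximum.
#'
#' @param spl_at_mic_dB SPL at the microphone (from
#'   [estimate_spl_at_mic()]).
#' @param d_bat_mic_m bat-to-microphone distance (m, >= 0.1).
#' @param frequency_kHz call peak frequency.
#' @param env a [environment_conditions()] object.
#' @param beam_compensation_dB the fixed compensation (default +3 dB).
#' @return source level at 10 cm, dB peSPL.
#' @export
estimate_source_level <- function(spl_at_mic_dB, d_bat_mic_m,
                                  frequency_kHz = 40,
                                  env = environment_conditions(),
                                  beam_compensation_dB = 3) {
  spl_at_mic_dB + transmission_loss(d_bat_mic_m, frequency_kHz, env) +
    beam_compensation_dB
}

#' Sound level arriving at the moth
#'
#' Forward-propagates the estimated source level (in the moth's
#' direction) over the bat-to-moth path. The +3 dB beam compensation is
#' applied once, inside [estimate_source_level()], and inherited here.
#'
#' @param source_level_10cm_dB source level from
#'   [estimate_source_level()].
#' @param d_bat_moth_m bat-to-moth distance (m, >= 0.1).
#' @param frequency_kHz call peak frequency.
#' @param env a [environment_conditions()] object.
#' @return SPL at the moth, dB peSPL.
#' @export
estimate_spl_at_moth <- function(source_level_10cm_dB, d_bat_moth_m,
                                 frequency_kHz = 40,
                                 env = environment_conditions()) {
  source_level_10cm_dB - transmission_loss(d_bat_moth_m, frequency_kHz, env)
}

#' Run the full calibration inverse over a scenario's received levels
#'
#' @param received a `received_levels` table (observed or simulated);
#'   must carry `recorded_level_db`, `freq_khz`, `mic_offaxis_deg`,
#'   `d_bat_mic_m`, `d_bat_moth_m`.
#' @param mic a [microphone_model()].
#' @param env a [environment_conditions()] object.
#' @param beam_compensation_dB see [estimate_source_level()].
#' @return the input with columns `est_spl_at_mic_db`,
#'   `est_source_level_db` and `est_spl_at_moth_db` appended.
#' @export
calibrate_received_levels <- function(received, mic = default_microphone(),
                                      env = environment_conditions(),
                                      beam_compensation_dB = 3) {
  need <- c("recorded_level_db", "freq_khz", "mic_offaxis_deg",
            "d_bat_mic_m", "d_bat_moth_m")
  miss <- setdiff(need, names(received))
  if (length(miss))
    stop("received levels table lacks column(s): ",
         paste(miss, collapse = ", "))
  spl_mic <- estimate_spl_at_mic(received$recorded_level_db,
                                 received$freq_khz,
                                 received$mic_offaxis_deg, mic)
  sl <- estimate_source_level(spl_mic, received$d_bat_mic_m,
                              received$freq_khz, env, beam_compensation_dB)
  spl_moth <- estimate_spl_at_moth(sl, received$d_bat_moth_m,
                                   received$freq_khz, env)
  received$est_spl_at_mic_db <- spl_mic
  received$est_source_level_db <- sl
  received$est_spl_at_moth_db <- spl_moth
  received
}

#' Per-event intensity and pulse-interval features
#'
#' The acoustic features attributed to one bat pass. Clicked events: the
#' mean level-at-moth of the two calls preceding the click, with the
#' pulse interval between those two calls (start-to-start). Non-clicked
#' events: the mean of the most intense call and its two neighbors, with
#' the pulse interval averaged over the two adjacent intervals. When the
#' most intense call is first or last in the series the available
#' neighbor is used and the event is flagged.
#'
#' @param times call emission times (s).
#' @param levels_at_moth_dB per-call level at the moth (dB).
#' @param click_time_s time of the first moth click, or `NA` if the moth
#'   did not click.
#' @return list with `intensity_dB`, `pulse_interval_ms`, `clicked`,
#'   `edge_flag`.
#' @export
click_event_features <- function(times, levels_at_moth_dB,
                                 click_time_s = NA_real_) {
  stopifnot(length(times) == length(levels_at_moth_dB))
  o <- order(times)
  times <- times[o]; lev <- levels_at_moth_dB[o]
  if (!is.na(click_time_s)) {
    prior <- which(times < click_time_s)
    if (length(prior) < 2L)
      stop("need at least 2 calls before the click to measure features")
    i2 <- utils::tail(prior, 2L)
    list(intensity_dB = mean(lev[i2]),
         pulse_interval_ms = (times[i2[2]] - times[i2[1]]) * 1000,
         clicked = TRUE, edge_flag = FALSE)
  } else {
    if (length(times) < 3L)
      stop("need at least 3 calls to measure non-click features")
    k <- which.max(lev)
    idx <- intersect((k - 1L):(k + 1L), seq_along(times))
    edge <- length(idx) < 3L
    if (edge) warning("max-level call lacks a neighbor; using available calls")
    list(intensity_dB = mean(lev[idx]),
         pulse_interval_ms = mean(diff(times[idx])) * 1000,
         clicked = FALSE, edge_flag = edge)
  }
}

#' Align per-attack call series on a common time zero
#'
#' @param attacks list of data frames, one per attack, each with columns
#'   `time_s` and the response column(s).
#' @param mode `"end"` aligns time zero at the last call of each attack;
#'   `"max_intensity"` aligns at the call of maximum `source_level_db`
#'   (ties broken by the earliest call).
#' @return the input list with `time_s` shifted so the alignment call is
#'   at 0 (inter-call intervals preserved exactly), and an `attack`
#'   id column added.
#' @export
align_attacks <- function(attacks, mode = c("end", "max_intensity")) {
  mode <- match.arg(mode)
  stopifnot(is.list(attacks), length(attacks) > 0)
  out <- lapply(seq_along(attacks), function(i) {
    a <- attacks[[i]]
    if (!nrow(a)) stop("attack ", i, " is empty")
    t0 <- if (mode == "end") max(a$time_s) else
      a$time_s[which.max(a$source_level_db)]  # which.max takes first tie
    a$time_s <- a$time_s - t0
    a$attack <- i
    a
  })
  out
}

#' Two-stage trend fit of attack-aligned responses
#'
#' A fixed-effects (within-attack centered) least-squares fit of a
#' response on time and optionally time squared: per-attack means of the
#' response and the regressors are removed, then the pooled slope
#' coefficients are estimated by ordinary least squares. This recovers
#' the shared time trend while absorbing per-attack intensity offsets,
#' in place of a full mixed-effects fit.
#'
#' @param aligned list of aligned attack data frames (from
#'   [align_attacks()]).
#' @param response name of the response column.
#' @param quadratic include a time-squared term.
#' @return list of class `trend_fit`: `B_time`, `B_time2` (NA when
#'   `quadratic = FALSE`), `offsets` (per-attack mean response), `r_squared`.
#' @export
fit_trend <- function(aligned, response = "est_spl_at_moth_db",
                      quadratic = TRUE) {
  stopifnot(is.list(aligned), length(aligned) > 0)
  df <- do.call(rbind, lapply(aligned, function(a)
    data.frame(attack = a$attack, time = a$time_s, y = a[[response]])))
  df <- df[stats::complete.cases(df), ]
  if (quadratic && any(table(df$attack) < 3L))
    stop("each attack needs >= 3 calls for a quadratic trend fit")
  center <- function(v, g) v - stats::ave(v, g)
  yc <- center(df$y, df$attack)
  X <- cbind(time = center(df$time, df$attack))
  if (quadratic) X <- cbind(X, time2 = center(df$time^2, df$attack))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design: time values do not identify the trend")
  beta <- qr.coef(qrX, yc)
  fitted <- as.numeric(X %*% beta)
  ss_res <- sum((yc - fitted)^2)
  ss_tot <- sum(yc^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  offsets <- tapply(df$y, df$attack, mean)
  structure(list(B_time = unname(beta["time"]),
                 B_time2 = if (quadratic) unname(beta["time2"]) else NA_real_,
                 offsets = offsets, r_squared = r2,
                 n_calls = nrow(df), n_attacks = length(unique(df$attack))),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> B_time = %.3f, B_time^2 = %s, R^2 = %.3f (%d calls, %d attacks)\n",
    x$B_time, ifelse(is.na(x$B_time2), "-", sprintf("%.3f", x$B_time2)),
    x$r_squared, x$n_calls, x$n_attacks))
  invisible(x)
}
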