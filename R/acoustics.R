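# Physical sound-propagation and sensor models: spherical spreading,
# atmospheric absorption, microphone corrections, sonar-beam directivity,
# and ensonified volume. All levels are dB (peSPL re 20 uPa for bat calls);
# source levels are referenced to REF_DISTANCE_M = 0.1 m from the bat.

#' Reference distance for source levels (meters)
#'
#' Source levels throughout the package are referenced to 10 cm from the
#' bat's mouth, the conventional reference for bat call intensities.
#' @export
REF_DISTANCE_M <- 0.1

#' Environmental conditions for sound propagation
#'
#' @param temperature_C air temperature in degrees Celsius, within
#'   \[-10, 50\].
#' @param relative_humidity_pct relative humidity in percent, within
#'   \[0, 100\].
#' @param pressure_kPa ambient atmospheric pressure in kPa (default one
#'   standard atmosphere).
#' @return an object of class `bat_environment`.
#' @examples
#' env <- environment_conditions(20, 50)
#' atmos_atten_coeff(40, env)
#' @export
environment_conditions <- function(temperature_C = 20,
                                   relative_humidity_pct = 50,
                                   pressure_kPa = 101.325) {
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L,
            is.numeric(relative_humidity_pct),
            length(relative_humidity_pct) == 1L)
  if (temperature_C < -10 || temperature_C > 50)
    stop("temperature_C must lie within [-10, 50] degrees C")
  if (relative_humidity_pct < 0 || relative_humidity_pct > 100)
    stop("relative_humidity_pct must lie within [0, 100]")
  if (pressure_kPa <= 0) stop("pressure_kPa must be positive")
  structure(list(temperature_C = temperature_C,
                 relative_humidity_pct = relative_humidity_pct,
                 pressure_kPa = pressure_kPa),
            class = "bat_environment")
}

#' @export
print.bat_environment <- function(x, ...) {
  cat(sprintf("<bat_environment> %.1f degC, %.0f%% RH, %.2f kPa\n",
              x$temperature_C, x$relative_humidity_pct, x$pressure_kPa))
  invisible(x)
}

#' Spherical spreading loss
#'
#' Loss in dB incurred by spherical spreading from `reference_m` out to
#' `distance_m`: `20 * log10(distance / reference)`. Additive over chained
#' distances.
#'
#' @param distance_m propagation distance in meters (> 0).
#' @param reference_m reference distance in meters (> 0), default 0.1 m.
#' @return loss in dB (negative if `distance_m < reference_m`).
#' @export
spreading_loss <- function(distance_m, reference_m = REF_DISTANCE_M) {
  if (any(!is.finite(distance_m)) || any(distance_m <= 0))
    stop("distance_m must be positive and finite")
  if (any(!is.finite(reference_m)) || any(reference_m <= 0))
    stop("reference_m must be positive and finite")
  20 * log10(distance_m / reference_m)
}

#' Atmospheric absorption coefficient (ISO 9613-1 pure-tone form)
#'
#' Classical plus molecular-relaxation absorption of sound in air,
#' evaluated from temperature, relative humidity and pressure. Valid over
#' the ultrasonic band used by echolocating bats; callers outside
#' 20--100 kHz get an error because the microphone calibration chain is
#' only specified there.
#'
#' @param frequency_kHz pure-tone frequency in kHz, within \[20, 100\].
#' @param env a [environment_conditions()] object.
#' @return absorption coefficient alpha in dB per meter (>= 0).
#' @references ISO 9613-1:1993, Acoustics -- Attenuation of sound during
#'   propagation outdoors.
#' @export
atmos_atten_coeff <- function(frequency_kHz, env = environment_conditions()) {
  stopifnot(inherits(env, "bat_environment"))
  if (any(!is.finite(frequency_kHz)) ||
      any(frequency_kHz < 20) || any(frequency_kHz > 100))
    stop("frequency_kHz must lie within [20, 100] kHz")
  f  <- frequency_kHz * 1000           # Hz
  pr <- 101.325                        # reference pressure, kPa
  pa <- env$pressure_kPa
  T0 <- 293.15; T01 <- 273.16
  TK <- env$temperature_C + 273.15
  # molar concentration of water vapour (%)
  psat <- pr * 10^(-6.8346 * (T01 / TK)^1.261 + 4.6151)
  h <- env$relative_humidity_pct * (psat / pr) / (pa / pr)
  frO <- (pa / pr) * (24 + 4.04e4 * h * (0.02 + h) / (0.391 + h))
  frN <- (pa / pr) * (TK / T0)^(-0.5) *
    (9 + 280 * h * exp(-4.170 * ((TK / T0)^(-1 / 3) - 1)))
  8.686 * f^2 * (
    1.84e-11 * (pa / pr)^(-1) * (TK / T0)^0.5 +
      (TK / T0)^(-2.5) * (
        0.01275 * exp(-2239.1 / TK) * frO / (frO^2 + f^2) +
        0.1068  * exp(-3352.0 / TK) * frN / (frN^2 + f^2)))
}

#' Total one-way transmission loss
#'
#' Spherical spreading from the 10 cm reference plus excess atmospheric
#' attenuation accumulated beyond the reference distance:
#' `20*log10(d/0.1) + alpha * (d - 0.1)`. Zero at the reference distance.
#'
#' @param distance_m propagation distance in meters (>= 0.1).
#' @param frequency_kHz call peak frequency in kHz.
#' @param env a [environment_conditions()] object.
#' @return loss in dB (>= 0).
#' @export
transmission_loss <- function(distance_m, frequency_kHz = 40,
                              env = environment_conditions()) {
  if (any(!is.finite(distance_m)) || any(distance_m < REF_DISTANCE_M))
    stop(sprintf("distance_m must be >= the %.1f m reference distance",
                 REF_DISTANCE_M))
  alpha <- atmos_atten_coeff(frequency_kHz, env)
  spreading_loss(distance_m, REF_DISTANCE_M) +
    alpha * (distance_m - REF_DISTANCE_M)
}

#' Sonar beam directivity model
#'
#' Two-parameter directivity for Myotis echolocation: search and approach
#' calls have a -6 dB full beam width of 80 degrees (half-width 40 deg);
#' terminal-buzz calls broaden to a 180 degree full width (half-width
#' 90 deg). Off-axis gain falls off parabolically in dB,
#' `gain(theta) = -6 * (theta / halfwidth)^2`, floored at `floor_dB`.
#'
#' @param halfwidth_search_approach_deg -6 dB half-width for search and
#'   approach phase calls (degrees).
#' @param halfwidth_buzz_deg -6 dB half-width for buzz phase calls.
#' @param floor_dB minimum (most negative) gain; the parabola is capped
#'   here to avoid unphysical rear nulls.
#' @return an object of class `beam_model`.
#' @export
beam_model <- function(halfwidth_search_approach_deg = 40,
                       halfwidth_buzz_deg = 90,
                       floor_dB = -40) {
  stopifnot(halfwidth_search_approach_deg > 0, halfwidth_buzz_deg > 0,
            floor_dB < 0)
  structure(list(halfwidth_search_approach_deg = halfwidth_search_approach_deg,
                 halfwidth_buzz_deg = halfwidth_buzz_deg,
                 floor_dB = floor_dB),
            class = "beam_model")
}

#' Beam directivity gain off the emission axis
#'
#' @param off_axis_deg angle between the beam axis and the receiver
#'   direction, degrees within \[0, 180\].
#' @param phase echolocation phase, one of `"search"`, `"approach"`,
#'   `"buzz"`; search and approach share a beam width.
#' @param beam a [beam_model()].
#' @return gain in dB: 0 on axis, -6 at the phase half-width,
#'   non-increasing in angle.
#' @export
beam_gain <- function(off_axis_deg, phase = c("search", "approach", "buzz"),
                      beam = beam_model()) {
  phase <- match.arg(phase)
  stopifnot(inherits(beam, "beam_model"))
  if (any(!is.finite(off_axis_deg)) ||
      any(off_axis_deg < 0) || any(off_axis_deg > 180))
    stop("off_axis_deg must lie within [0, 180] degrees")
  hw <- if (phase == "buzz") beam$halfwidth_buzz_deg
        else beam$halfwidth_search_approach_deg
  pmax(-6 * (off_axis_deg / hw)^2, beam$floor_dB)
}

#' Microphone response model
#'
#' Holds the frequency-response and directionality calibration tables of a
#' recording microphone plus its pose. `freq_response` gives the gain of
#' the recording chain relative to a reference microphone (dB, so the
#' correction to ADD to a recorded level is `-gain`); `directionality`
#' gives the off-axis gain at calibration frequencies.
#'
#' @param freq_response data frame with columns `frequency_khz`
#'   (5 kHz steps over 20--100) and `gain_db`.
#' @param directionality data frame with columns `frequency_khz`,
#'   `angle_deg` (22.5 degree steps over 0--180) and `gain_db`; on-axis
#'   gain must be 0 dB.
#' @param position microphone position, numeric 3-vector (m).
#' @param axis microphone pointing direction, numeric 3-vector
#'   (normalized internally).
#' @return an object of class `microphone_model`.
#' @seealso [default_microphone()] for the bundled miniature-microphone
#'   calibration.
#' @export
microphone_model <- function(freq_response, directionality,
                             position = c(0, 0, 0), axis = c(1, 0, 0)) {
  need <- function(df, cols, nm) {
    if (!is.data.frame(df) || !all(cols %in% names(df)))
      stop(sprintf("%s must be a data frame with columns: %s",
                   nm, paste(cols, collapse = ", ")))
  }
  need(freq_response, c("frequency_khz", "gain_db"), "freq_response")
  need(directionality, c("frequency_khz", "angle_deg", "gain_db"),
       "directionality")
  freq_response <- freq_response[order(freq_response$frequency_khz), ]
  on_axis <- directionality[directionality$angle_deg == 0, "gain_db"]
  if (length(on_axis) && any(abs(on_axis) > 1e-9))
    stop("directionality gain must be 0 dB on axis (angle_deg == 0)")
  stopifnot(length(position) == 3L, length(axis) == 3L)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be a non-zero 3-vector")
  structure(list(freq_response = freq_response,
                 directionality = directionality,
                 position = as.numeric(position),
                 axis = as.numeric(axis) / nrm),
            class = "microphone_model")
}

#' Default miniature-microphone calibration
#'
#' Synthetic calibration emulating the published description of the
#' miniature electret used for field recording: response flat (within
#' +/- 1.5 dB) from 20--40 kHz, then sensitivity dropping ~5 dB per
#' 10 kHz from 40--100 kHz; fairly omnidirectional with adjustments of a
#' few dB. Gains are relative to the reference measuring chain, so the
#' additive correction returned by [mic_correction()] is their negative.
#'
#' @param position,axis microphone pose (see [microphone_model()]).
#' @return a `microphone_model`.
#' @export
default_microphone <- function(position = c(0, 0, 0), axis = c(1, 0, 0)) {
  f <- seq(20, 100, by = 5)
  gain <- ifelse(f <= 40, 0, -5 * (f - 40) / 10)
  fr <- data.frame(frequency_khz = f, gain_db = gain)
  ang <- seq(0, 180, by = 22.5)
  dirs <- do.call(rbind, lapply(c(20, 30, 40, 50, 60), function(fk) {
    # gentle cardioid-like droop, within the +/- 2-4 dB reported envelope
    amp <- 2 + 2 * (fk - 20) / 40
    data.frame(frequency_khz = fk, angle_deg = ang,
               gain_db = -amp * (1 - cos(ang * pi / 180)) / 2)
  }))
  microphone_model(fr, dirs, position = position, axis = axis)
}

# bilinear interpolation helper on a (frequency, angle) table
.interp1 <- function(x, y, x0) {
  stats::approx(x, y, xout = x0, rule = 1)$y
}

#' Microphone correction from recorded level to true SPL
#'
#' The dB correction to add to a level recorded through the microphone
#' chain to obtain the true sound pressure level at the microphone,
#' combining the inverse frequency response and the inverse off-axis
#' directionality (linear interpolation between calibration nodes in both
#' frequency and angle; directionality is taken at the nearest bracketing
#' calibration frequencies, 20--60 kHz, and clamped outside).
#'
#' @param frequency_kHz call peak frequency, within the calibration range.
#' @param off_axis_deg sound incidence angle off the microphone axis,
#'   within \[0, 180\].
#' @param mic a [microphone_model()].
#' @return correction in dB to add to the recorded level.
#' @export
mic_correction <- function(frequency_kHz, off_axis_deg,
                           mic = default_microphone()) {
  stopifnot(inherits(mic, "microphone_model"))
  fr <- mic$freq_response
  if (any(frequency_kHz < min(fr$frequency_khz)) ||
      any(frequency_kHz > max(fr$frequency_khz)))
    stop(sprintf("frequency_kHz outside the calibrated range [%g, %g] kHz",
                 min(fr$frequency_khz), max(fr$frequency_khz)))
  if (any(off_axis_deg < 0) || any(off_axis_deg > 180))
    stop("off_axis_deg must lie within [0, 180]")
  g_freq <- .interp1(fr$frequency_khz, fr$gain_db, frequency_kHz)
  dt <- mic$directionality
  fk <- sort(unique(dt$frequency_khz))
  g_dir <- mapply(function(f0, a0) {
    fc <- min(max(f0, min(fk)), max(fk))   # clamp to directionality range
    lo <- max(fk[fk <= fc]); hi <- min(fk[fk >= fc])
    glo <- .interp1(dt$angle_deg[dt$frequency_khz == lo],
                    dt$gain_db[dt$frequency_khz == lo], a0)
    if (hi == lo) return(glo)
    ghi <- .interp1(dt$angle_deg[dt$frequency_khz == hi],
                    dt$gain_db[dt$frequency_khz == hi], a0)
    glo + (ghi - glo) * (fc - lo) / (hi - lo)
  }, frequency_kHz, off_axis_deg)
  -(g_freq + g_dir)
}

#' Volume ensonified above a sound-level threshold
#'
#' Volume of space receiving at least `threshold_dB` from a single call of
#' given on-axis source level, integrating `r(theta)^3 / 3` over solid
#' angle for an axisymmetric beam, where `r(theta)` solves
#' `SL + beam_gain(theta) - transmission_loss(r) = threshold`.
#'
#' @param source_level_dB on-axis source level at 10 cm (dB peSPL).
#' @param beam a [beam_model()].
#' @param phase echolocation phase selecting the beam width.
#' @param threshold_dB ensonification threshold (dB SPL), e.g. 90.
#' @param frequency_kHz call frequency for atmospheric absorption.
#' @param env a [environment_conditions()] object.
#' @param n_theta number of polar quadrature nodes.
#' @param alpha_db_per_m optional fixed absorption coefficient overriding
#'   the ISO 9613-1 value (0 gives pure spherical spreading, for which
#'   the omnidirectional volume has the closed form `(4/3) pi r^3`).
#' @return volume in cubic meters (0 when the source never reaches the
#'   threshold even at the reference distance).
#' @export
ensonified_volume <- function(source_level_dB, beam = beam_model(),
                              phase = "approach", threshold_dB = 90,
                              frequency_kHz = 40,
                              env = environment_conditions(),
                              n_theta = 181L, alpha_db_per_m = NULL) {
  alpha <- if (is.null(alpha_db_per_m)) atmos_atten_coeff(frequency_kHz, env)
           else alpha_db_per_m
  stopifnot(alpha >= 0)
  r_solve <- function(excess_dB) {
    # largest r with 20*log10(r/0.1) + alpha*(r-0.1) <= excess (monotone)
    if (excess_dB <= 0) return(0)  # below threshold already at 10 cm
    r0 <- REF_DISTANCE_M * 10^(excess_dB / 20)  # alpha = 0 bound
    stats::uniroot(function(r) spreading_loss(r) +
                     alpha * (r - REF_DISTANCE_M) - excess_dB,
                   lower = REF_DISTANCE_M, upper = r0 + REF_DISTANCE_M,
                   tol = 1e-10)$root
  }
  if (source_level_dB <= threshold_dB) return(0)
  theta <- seq(0, 180, length.out = n_theta)
  g <- beam_gain(theta, phase, beam)
  r <- vapply(source_level_dB + g - threshold_dB, r_solve, numeric(1))
  integrand <- (r^3 / 3) * sin(theta * pi / 180)
  # trapezoid in theta, times 2*pi from azimuthal symmetry
  h <- pi / (n_theta - 1)
  2 * pi * h * (sum(integrand) - (integrand[1] + integrand[n_theta]) / 2)
}

#' Read microphone calibration tables from delimited text
#'
#' Loads a frequency-response table (`frequency_khz, gain_db`) and a
#' directionality table (`frequency_khz, angle_deg, gain_db`) from CSV.
#' The package ships a synthetic example pair under
#' `system.file("extdata", package = "sonarthreat")` emulating the
#' miniature field microphone.
#'
#' @param freq_response_path CSV path for the frequency response.
#' @param directionality_path CSV path for the directionality table.
#' @param position,axis microphone pose (see [microphone_model()]).
#' @return a [microphone_model()].
#' @export
read_microphone_tables <- function(freq_response_path, directionality_path,
                                   position = c(0, 0, 0),
                                   axis = c(1, 0, 0)) {
  microphone_model(utils::read.csv(freq_response_path),
                   utils::read.csv(directionality_path),
                   position = position, axis = axis)
}
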