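# File schemas and the end-to-end pipeline: scenario bundles are plain
# directories (calls.csv, tracks.csv, meta.json); models and reports are
# JSON. No binary formats are needed at this data scale.

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}
.read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", file,
                 paste(miss, collapse = ", ")))
}

#' Write a scenario bundle to a directory
#'
#' Serializes an attack scenario as `calls.csv` (the call table),
#' `tracks.csv` (long-format 3-D tracks: time_s, object_id, x_m, y_m,
#' z_m), and `meta.json` (threat type, seed, environment, geometry).
#'
#' @param scn an [make_attack_scenario()] scenario.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_scenario_bundle <- function(scn, path) {
  stopifnot(inherits(scn, "attack_scenario"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  .write_csv(as.data.frame(scn$calls), file.path(path, "calls.csv"))
  tr <- scn$bat_track
  tracks <- data.frame(time_s = tr$times, object_id = "bat",
                       x_m = tr$positions[, 1], y_m = tr$positions[, 2],
                       z_m = tr$positions[, 3])
  statics <- list(focal_moth = scn$focal_moth, mic = scn$mic$position)
  if (!is.null(scn$neighbor_moth)) statics$neighbor_moth <- scn$neighbor_moth
  for (nm in names(statics))
    tracks <- rbind(tracks,
                    data.frame(time_s = 0, object_id = nm,
                               x_m = statics[[nm]][1], y_m = statics[[nm]][2],
                               z_m = statics[[nm]][3]))
  .write_csv(tracks, file.path(path, "tracks.csv"))
  meta <- list(threat_type = scn$threat_type, seed = scn$seed,
               capture_time_s = scn$capture_time_s,
               environment = unclass(scn$env),
               mic_axis = scn$mic$axis,
               units = list(time = "s", position = "m", level = "dB peSPL",
                            frequency = "kHz"))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scenario bundle from a directory
#'
#' Schema-validated inverse of [write_scenario_bundle()]; unknown extra
#' columns in the CSVs are preserved.
#'
#' @param path bundle directory containing `calls.csv`, `tracks.csv`,
#'   `meta.json`.
#' @return an `attack_scenario`.
#' @export
read_scenario_bundle <- function(path) {
  for (f in c("calls.csv", "tracks.csv", "meta.json"))
    if (!file.exists(file.path(path, f)))
      stop("scenario bundle is missing ", f)
  calls <- .read_csv(file.path(path, "calls.csv"))
  .require_cols(calls, c("time_s", "pulse_interval_ms", "freq_khz",
                         "duration_ms", "source_level_db",
                         "beam_offaxis_deg", "phase"), "calls.csv")
  calls$phase <- factor(calls$phase, levels = PHASES)
  class(calls) <- c("call_sequence", "data.frame")
  tracks <- .read_csv(file.path(path, "tracks.csv"))
  .require_cols(tracks, c("time_s", "object_id", "x_m", "y_m", "z_m"),
                "tracks.csv")
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  bat <- tracks[tracks$object_id == "bat", ]
  if (!nrow(bat)) stop("tracks.csv contains no 'bat' track")
  one_point <- function(id) {
    r <- tracks[tracks$object_id == id, ]
    if (!nrow(r)) return(NULL)
    as.numeric(r[1, c("x_m", "y_m", "z_m")])
  }
  focal <- one_point("focal_moth")
  if (is.null(focal)) stop("tracks.csv contains no 'focal_moth' position")
  micp <- one_point("mic")
  if (is.null(micp)) stop("tracks.csv contains no 'mic' position")
  neighbor <- one_point("neighbor_moth")
  env <- environment_conditions(meta$environment$temperature_C,
                                meta$environment$relative_humidity_pct,
                                meta$environment$pressure_kPa)
  target <- if (identical(meta$threat_type, "false") && !is.null(neighbor))
    neighbor else focal
  structure(list(threat_type = meta$threat_type,
                 bat_track = raw_track(bat$time_s,
                                       as.matrix(bat[, c("x_m", "y_m", "z_m")])),
                 focal_moth = focal, neighbor_moth = neighbor,
                 target = target,
                 mic = default_microphone(position = micp,
                                          axis = as.numeric(meta$mic_axis)),
                 env = env, calls = calls,
                 capture_time_s = meta$capture_time_s,
                 params = NULL, seed = meta$seed),
            class = "attack_scenario")
}

#' Run configuration for the end-to-end pipeline
#'
#' @param seed master seed; per-scenario seeds are derived from it.
#' @param n_real,n_false number of real/false threat scenarios.
#' @param noise_sd_dB recorded-level measurement noise.
#' @param env a [environment_conditions()] object.
#' @param params a [scenario_params()] object.
#' @param out_dir output directory (`NULL` = no files written).
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_real = 5L, n_false = 9L,
                       noise_sd_dB = 0, env = environment_conditions(),
                       params = scenario_params(env = env),
                       out_dir = NULL) {
  stopifnot(n_real >= 1L, n_false >= 1L, noise_sd_dB >= 0)
  structure(list(seed = as.integer(seed), n_real = as.integer(n_real),
                 n_false = as.integer(n_false), noise_sd_dB = noise_sd_dB,
                 env = env, params = params, out_dir = out_dir),
            class = "run_config")
}

#' Simulate, calibrate and analyze an ensemble of attacks
#'
#' The end-to-end pipeline: generates `n_real` real-threat and `n_false`
#' false-threat scenarios, forward-simulates their received levels (with
#' optional measurement noise), runs the calibration inverse, fits the
#' real-vs-false discrimination model on (log10 pulse interval,
#' level-at-moth), extracts p = 0.5 and p = 0.75 threshold curves, and
#' computes per-phase ROC/AUR separability. Identical config and seed
#' give an identical report. When `config$out_dir` is set, writes
#' `received_levels.csv`, `thresholds.csv`, `model.json`, `roc.json` and
#' `report.json` there.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_report`: `calibrated` (one data frame
#'   per scenario), `model`, `curves` (p = 0.5, p = 0.75), `roc` (per
#'   phase), `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(nm, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] %.2f s", nm, proc.time()[["elapsed"]] - t0))
    res
  }
  types <- rep(c("real", "false"), c(config$n_real, config$n_false))
  seeds <- config$seed * 1000L + seq_along(types)
  scns <- stage("simulate", lapply(seq_along(types), function(i)
    make_attack_scenario(types[i], config$params, seed = seeds[i])))
  calib <- stage("calibrate", lapply(seq_along(scns), function(i) {
    rl <- simulate_received_levels(scns[[i]],
                                   noise_sd_dB = config$noise_sd_dB,
                                   seed = seeds[i] + 500L)
    cal <- calibrate_received_levels(rl, scns[[i]]$mic, config$env)
    cal$threat_type <- types[i]
    cal$attack <- i
    cal
  }))
  all_calls <- do.call(rbind, calib)
  ok <- !is.na(all_calls$pulse_interval_ms)
  pts <- threat_points(all_calls$pulse_interval_ms[ok],
                       all_calls$est_spl_at_moth_db[ok])
  is_real <- all_calls$threat_type[ok] == "real"
  model <- stage("discriminate",
                 fit_discrimination(pts[is_real, ], pts[!is_real, ]))
  curves <- stage("thresholds", list(
    p0.5 = threshold_curve_from_model(model, 0.5),
    p0.75 = threshold_curve_from_model(model, 0.75)))
  roc <- stage("roc", {
    ph <- classify_phase(all_calls$pulse_interval_ms[ok])
    lev <- all_calls$est_spl_at_moth_db[ok]
    out <- lapply(PHASES, function(p) {
      sel <- ph == p
      if (sum(sel & is_real) && sum(sel & !is_real))
        auc_real_vs_false(lev[sel & is_real], lev[sel & !is_real])
      else NULL
    })
    names(out) <- PHASES
    out
  })
  report <- structure(list(calibrated = calib, model = model,
                           curves = curves, roc = roc, config = config),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_report(report)
  report
}

#' Write pipeline outputs to the configured directory
#'
#' @param report a `pipeline_report` whose config has `out_dir` set.
#' @return the output directory, invisibly.
#' @export
write_pipeline_report <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- report$config$out_dir
  if (is.null(out)) stop("config$out_dir is not set")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  .write_csv(do.call(rbind, report$calibrated),
             file.path(out, "received_levels.csv"))
  thr <- do.call(rbind, lapply(names(report$curves), function(nm)
    data.frame(curve = nm,
               pi_ms = report$curves[[nm]]$pulse_interval_ms,
               threshold_db = report$curves[[nm]]$threshold_dB)))
  .write_csv(thr, file.path(out, "thresholds.csv"))
  m <- report$model
  jsonlite::write_json(
    list(real = list(mean = m$real$mean, cov = m$real$cov),
         false = list(mean = m$false$mean, cov = m$false$cov),
         priors = m$priors, n = as.list(m$n)),
    file.path(out, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, matrix = "rowmajor")
  jsonlite::write_json(
    lapply(Filter(Negate(is.null), report$roc), unclass),
    file.path(out, "roc.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  cfg <- report$config
  jsonlite::write_json(
    list(seed = cfg$seed, n_real = cfg$n_real, n_false = cfg$n_false,
         noise_sd_dB = cfg$noise_sd_dB, environment = unclass(cfg$env)),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out)
}
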