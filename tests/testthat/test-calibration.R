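# The audio-calibration inverse and attack-aligned trend fits

test_that("spl at mic inverts the sensor response", {
  mic <- default_microphone()
  # flat-band on-axis: identity
  expect_equal(estimate_spl_at_mic(80, 40, 0, mic), 80)
  # reduced sensitivity at 60 kHz: recorded + ~10 dB
  expect_equal(estimate_spl_at_mic(80, 60, 0, mic), 90)
  # all-zero table: identity at any angle
  fr <- data.frame(frequency_khz = seq(20, 100, 5), gain_db = 0)
  dr <- expand.grid(frequency_khz = c(20, 40, 60),
                    angle_deg = seq(0, 180, 22.5))
  dr$gain_db <- 0
  mic0 <- microphone_model(fr, dr)
  expect_equal(estimate_spl_at_mic(77.7, 53, 131, mic0), 77.7)
  expect_error(estimate_spl_at_mic(80, 150, 0, mic), "range")
})

test_that("source level estimation composes loss terms plus 3 dB", {
  expect_equal(estimate_source_level(80, 0.1, 40, ENV_REF), 83)
  alpha <- atmos_atten_coeff(40, ENV_REF)
  expect_equal(estimate_source_level(80, 2, 40, ENV_REF),
               80 + 20 * log10(2 / 0.1) + alpha * 1.9 + 3,
               tolerance = 1e-10)
  expect_error(estimate_source_level(80, 0.05, 40, ENV_REF), "reference")
  # level at the moth undoes the propagation without re-adding the 3 dB
  expect_equal(estimate_spl_at_moth(110, 0.1, 40, ENV_REF), 110)
  expect_equal(estimate_spl_at_moth(110, 2, 40, ENV_REF),
               110 - transmission_loss(2, 40, ENV_REF))
})

test_that("idealized forward model round-trips to < 1e-6 dB", {
  for (seed in c(1, 7, 23)) {
    for (type in c("real", "false")) {
      scn <- quick_scenario(type, seed = seed)
      cal <- calibrated_scenario(scn, idealized = TRUE)
      # source level in the moth's direction = on-axis SL + beam gain
      sl_true <- cal$source_level_db + cal$beam_gain_moth_db
      expect_lt(max(abs(cal$est_source_level_db - sl_true)), 1e-6)
      expect_lt(max(abs(cal$est_spl_at_moth_db - cal$true_spl_at_moth_db)),
                1e-6)
    }
  }
})

test_that("realistic beam geometry leaves a bounded recovery bias", {
  scn <- quick_scenario("real", seed = 5)
  cal <- calibrated_scenario(scn, idealized = FALSE)
  bias <- cal$est_spl_at_moth_db - cal$true_spl_at_moth_db
  bound <- abs(cal$beam_gain_moth_db - cal$beam_gain_mic_db - 3)
  expect_true(all(abs(bias) <= bound + 1e-9))
})

test_that("noisy gain-control recovery averages back to the setpoint", {
  scn <- quick_scenario("real", seed = 3)
  t_lock <- attr(scn$calls, "t_lock")
  means <- vapply(1:20, function(s) {
    cal <- calibrated_scenario(scn, noise_sd_dB = 1, idealized = TRUE,
                               seed = s)
    mean(cal$est_spl_at_moth_db[cal$time_s >= t_lock])
  }, numeric(1))
  expect_gt(sum(scn$calls$time_s >= t_lock), 30)
  expect_lt(abs(mean(means) - 95.3), 0.5)
})

test_that("click-event features follow the two-call / three-call rules", {
  # clicked: mean of the two calls preceding the click, their start-to-start PI
  f <- click_event_features(times = c(0.00, 0.04, 0.08, 0.12),
                            levels_at_moth_dB = c(85, 90, 94, 97),
                            click_time_s = 0.10)
  expect_equal(f$intensity_dB, 92)
  expect_equal(f$pulse_interval_ms, 40)
  expect_true(f$clicked)
  # non-clicked: most intense call and both neighbors
  g <- click_event_features(times = c(0, 0.05, 0.10),
                            levels_at_moth_dB = c(88, 95, 91))
  expect_equal(g$intensity_dB, mean(c(88, 95, 91)), tolerance = 1e-9)
  expect_equal(g$pulse_interval_ms, 50)
  # boundary: exactly two calls before the click is fine, one is not
  expect_silent(click_event_features(c(0, 0.04), c(90, 94), 0.05))
  expect_error(click_event_features(c(0, 0.04), c(90, 94), 0.02),
               "at least 2")
  # max-level call at the edge: flagged, uses available neighbor
  expect_warning(
    h <- click_event_features(c(0, 0.05, 0.10), c(96, 92, 90)),
    "neighbor")
  expect_true(h$edge_flag)
  expect_equal(h$intensity_dB, mean(c(96, 92)))
})

test_that("attack alignment fixes time zero without distorting intervals", {
  a1 <- data.frame(time_s = c(0, 0.1, 0.25), source_level_db = c(100, 118, 110))
  a2 <- data.frame(time_s = c(0.5, 0.8), source_level_db = c(105, 105))
  by_end <- align_attacks(list(a1, a2), "end")
  expect_equal(by_end[[1]]$time_s, c(-0.25, -0.15, 0))
  expect_equal(by_end[[2]]$time_s, c(-0.3, 0))
  by_max <- align_attacks(list(a1, a2), "max_intensity")
  expect_equal(by_max[[1]]$time_s, c(-0.1, 0, 0.15))
  # tie broken by the earliest call
  expect_equal(by_max[[2]]$time_s, c(0, 0.3))
  # intervals preserved exactly
  expect_equal(diff(by_end[[1]]$time_s), diff(a1$time_s))
  # single-call attack sits at zero in either mode
  single <- list(data.frame(time_s = 1.23, source_level_db = 100))
  expect_equal(align_attacks(single, "end")[[1]]$time_s, 0)
  expect_equal(align_attacks(single, "max_intensity")[[1]]$time_s, 0)
})

test_that("trend fitting recovers exact synthetic quadratics", {
  set.seed(8)
  attacks <- lapply(1:4, function(i) {
    t <- seq(-1, 0, length.out = 12)
    data.frame(time_s = t, attack = i,
               y = 5 * i + 30 * t - 12 * t^2)   # per-attack offsets
  })
  fit <- fit_trend(attacks, response = "y", quadratic = TRUE)
  expect_lt(abs(fit$B_time - 30), 1e-8)
  expect_lt(abs(fit$B_time2 + 12), 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # constant response: zero slope, zero R^2
  flat <- lapply(1:3, function(i)
    data.frame(time_s = seq(-1, 0, length.out = 5), attack = i, y = 7))
  f0 <- fit_trend(flat, response = "y", quadratic = FALSE)
  expect_equal(f0$B_time, 0)
  expect_equal(f0$r_squared, 0)
  # rank deficiency is an error
  degen <- list(data.frame(time_s = rep(0, 4), attack = 1, y = rnorm(4)))
  expect_error(fit_trend(degen, response = "y"), "rank")
})

test_that("false-threat ensembles show falling levels at the focal moth", {
  cals <- lapply(1:5, function(s) {
    scn <- quick_scenario("false", seed = s)
    cal <- calibrated_scenario(scn, noise_sd_dB = 1, seed = s)
    cal
  })
  aligned <- align_attacks(cals, "end")
  # final half second of each attack
  aligned <- lapply(aligned, function(a) a[a$time_s >= -0.5, ])
  fit <- fit_trend(aligned, response = "est_spl_at_moth_db",
                   quadratic = FALSE)
  expect_lt(fit$B_time, 0)
})
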