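# Sound propagation, sensor and beam models

test_that("spherical spreading follows 20 log10(d/ref) and chains additively", {
  expect_equal(spreading_loss(0.1, 0.1), 0)
  expect_equal(spreading_loss(1.0, 0.1), 20)
  expect_equal(spreading_loss(2.0, 1.0), 6.0206, tolerance = 1e-4)
  # additivity over chained distances
  expect_equal(spreading_loss(3.7, 0.1),
               spreading_loss(3.7, 0.6) + spreading_loss(0.6, 0.1))
  expect_error(spreading_loss(0), "positive")
  expect_error(spreading_loss(-1), "positive")
})

test_that("atmospheric absorption matches the published ISO 9613-1 values", {
  expect_equal(atmos_atten_coeff(40, ENV_REF), ALPHA_REF[["40_20_50"]],
               tolerance = 1e-4)
  expect_equal(atmos_atten_coeff(20, ENV_REF), ALPHA_REF[["20_20_50"]],
               tolerance = 1e-4)
  expect_equal(atmos_atten_coeff(60, environment_conditions(25, 30)),
               ALPHA_REF[["60_25_30"]], tolerance = 1e-4)
  expect_error(atmos_atten_coeff(10, ENV_REF), "20, 100")
  expect_error(atmos_atten_coeff(150, ENV_REF), "20, 100")
})

test_that("absorption increases with frequency over the ultrasonic band", {
  for (env in list(ENV_REF, environment_conditions(30, 80),
                   environment_conditions(5, 20))) {
    a <- atmos_atten_coeff(seq(20, 100, by = 5), env)
    expect_true(all(diff(a) > 0))
    expect_true(all(a > 0))
  }
})

test_that("transmission loss is zero at the reference and strictly increasing", {
  expect_equal(transmission_loss(0.1, 40, ENV_REF), 0)
  alpha <- atmos_atten_coeff(40, ENV_REF)
  expect_equal(transmission_loss(1.0, 40, ENV_REF), 20 + alpha * 0.9,
               tolerance = 1e-10)
  d <- seq(0.1, 6, by = 0.05)
  expect_true(all(diff(transmission_loss(d, 40, ENV_REF)) > 0))
  expect_error(transmission_loss(0.05, 40, ENV_REF), "reference")
})

test_that("source level round-trips through transmission loss", {
  set.seed(7)
  for (i in 1:25) {
    d <- runif(1, 0.1, 6); sl <- runif(1, 70, 125)
    received <- sl - transmission_loss(d, 40, ENV_REF)
    expect_lt(abs(received + transmission_loss(d, 40, ENV_REF) - sl), 1e-9)
  }
})

test_that("beam gain meets the phase-specific -6 dB widths and is monotone", {
  expect_equal(beam_gain(0, "search"), 0)
  expect_equal(beam_gain(0, "buzz"), 0)
  expect_equal(beam_gain(40, "approach"), -6)   # 80 deg full width
  expect_equal(beam_gain(40, "search"), -6)
  expect_equal(beam_gain(90, "buzz"), -6)       # 180 deg full width
  ang <- seq(0, 180, by = 1)
  for (ph in c("search", "approach", "buzz"))
    expect_true(all(diff(beam_gain(ang, ph)) <= 0))
  expect_gte(min(beam_gain(ang, "search")), beam_model()$floor_dB)
  expect_error(beam_gain(200, "search"), "0, 180")
})

test_that("microphone correction inverts the bundled response tables", {
  mic <- default_microphone()
  # flat band: zero correction on axis at and below 40 kHz
  expect_equal(mic_correction(40, 0, mic), 0)
  expect_equal(mic_correction(25, 0, mic), 0)
  # ~5 dB lost sensitivity per 10 kHz above 40 -> +10 dB correction at 60
  expect_equal(mic_correction(60, 0, mic), 10)
  # interpolation identity at a table node
  node <- mic$freq_response[mic$freq_response$frequency_khz == 75, ]
  expect_equal(mic_correction(75, 0, mic), -node$gain_db)
  # directionality adjustments stay within the reported few-dB envelope
  grid <- expand.grid(f = c(20, 30, 40, 50, 60), a = seq(0, 180, by = 22.5))
  dir_part <- mapply(function(f, a)
    mic_correction(f, a, mic) - mic_correction(f, 0, mic), grid$f, grid$a)
  expect_true(all(abs(dir_part) <= 4 + 1e-9))
  expect_error(mic_correction(110, 0, mic), "range")
})

test_that("custom microphone tables are validated and interpolated", {
  fr <- data.frame(frequency_khz = c(20, 40, 60), gain_db = c(0, -2, -8))
  dr <- data.frame(frequency_khz = rep(c(20, 60), each = 2),
                   angle_deg = rep(c(0, 90), 2),
                   gain_db = c(0, -2, 0, -4))
  mic <- microphone_model(fr, dr)
  expect_equal(mic_correction(30, 0, mic), 1)         # freq interp
  expect_equal(mic_correction(40, 45, mic), 2 + 1.5)  # angle+freq interp
  dr_bad <- dr; dr_bad$gain_db[1] <- 1
  expect_error(microphone_model(fr, dr_bad), "0 dB on axis")
})

test_that("ensonified volume recovers the closed-form omnidirectional sphere", {
  omni <- beam_model(1e7, 1e7)
  # SL - threshold = 20 dB and alpha = 0 puts the iso-surface at r = 1 m
  v <- ensonified_volume(110, omni, "search", threshold_dB = 90,
                         alpha_db_per_m = 0)
  expect_equal(v, 4 * pi / 3, tolerance = 1e-3)
  # quadrature convergence: doubling resolution moves it < 0.1 %
  v2 <- ensonified_volume(110, omni, "search", threshold_dB = 90,
                          alpha_db_per_m = 0, n_theta = 361L)
  expect_lt(abs(v2 - v) / v, 1e-3)
})

test_that("ensonified volume shrinks with threshold and with absorption", {
  v90 <- ensonified_volume(110, phase = "approach", threshold_dB = 90,
                           env = ENV_REF)
  v95 <- ensonified_volume(110, phase = "approach", threshold_dB = 95,
                           env = ENV_REF)
  expect_gt(v90, v95)
  v_noabs <- ensonified_volume(110, phase = "approach", threshold_dB = 90,
                               alpha_db_per_m = 0)
  expect_gt(v_noabs, v90)
  # below threshold at the source: nothing is ensonified
  expect_equal(ensonified_volume(85, phase = "approach", threshold_dB = 90), 0)
  # the buzz beam is broader, so at equal source level it fills more space
  vb <- ensonified_volume(110, phase = "buzz", threshold_dB = 90,
                          env = ENV_REF)
  expect_gt(vb, v90)
})

test_that("bundled microphone tables load from delimited text", {
  ext <- system.file("extdata", package = "sonarthreat")
  mic <- read_microphone_tables(file.path(ext, "mic_freq_response.csv"),
                                file.path(ext, "mic_directionality.csv"))
  expect_s3_class(mic, "microphone_model")
  expect_equal(mic_correction(40, 0, mic), 0)
  expect_equal(mic_correction(60, 0, mic), 10)
})

test_that("environment validation enforces physical ranges", {
  expect_error(environment_conditions(-20, 50), "temperature")
  expect_error(environment_conditions(20, 120), "humidity")
  expect_s3_class(environment_conditions(0, 0), "bat_environment")
})
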