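# Threshold extraction, two-class Gaussian discrimination, ROC, and
# clicking/non-clicking pass classification

test_that("ramp threshold readout takes the pulse preceding the click", {
  r <- make_ramp_playback(100)
  expect_equal(extract_threshold_from_ramp(r, 4.95), 94.5)
  # click right after the first pulse: threshold is the 70 dB start
  expect_equal(extract_threshold_from_ramp(r, 0.01), 70)
  expect_true(is.na(extract_threshold_from_ramp(r, NA)))
  expect_error(extract_threshold_from_ramp(r, -1), "precedes")
})

test_that("phase mean thresholds average representative pulse intervals", {
  curve <- threshold_curve(c(4, 7, 12, 20, 30, 45, 60, 80, 100),
                           c(101, 99, 92, 84, 84, 86, 89, 95, 97))
  m <- phase_mean_thresholds(curve)
  expect_equal(unname(m["search"]), 96)
  expect_equal(unname(m["approach"]), mean(c(84, 84, 86)))
  expect_equal(unname(m["buzz"]), 100)
  # approach-band minimum: approach mean below search and buzz means
  expect_lt(m["approach"], m["search"])
  expect_lt(m["approach"], m["buzz"])
  # transitional 12 and 60 ms intervals alone cannot give phase means
  expect_error(phase_mean_thresholds(threshold_curve(c(12, 60), c(90, 90))),
               "missing representative")
})

test_that("threshold curves interpolate in log pulse interval", {
  curve <- threshold_curve(c(10, 100), c(80, 90))
  expect_equal(threshold_at(curve, 10), 80)
  expect_equal(threshold_at(curve, 100), 90)
  # halfway in log10: sqrt(10*100) ~ 31.6 ms -> 85 dB
  expect_equal(threshold_at(curve, sqrt(1000)), 85, tolerance = 1e-9)
  expect_error(threshold_curve(c(10, 10), c(80, 81)), "increasing")
  expect_error(threshold_curve(c(10, 20), c(50, 80)), "60, 130")
})

test_that("discrimination posteriors agree with an independent QDA", {
  set.seed(14)
  real <- threat_points(exp(runif(60, log(4), log(100))),
                        rnorm(60, 95, 4))
  false <- threat_points(exp(runif(60, log(4), log(100))),
                         rnorm(60, 82, 5))
  model <- fit_discrimination(real, false)
  q <- MASS::qda(rbind(real, false),
                 grouping = factor(rep(c("real", "false"), each = 60)),
                 prior = c(false = 0.5, real = 0.5))
  test_pts <- data.frame(log_pi = runif(100, 0.6, 2),
                         intensity_db = runif(100, 70, 110))
  mine <- posterior_real(model, test_pts$log_pi, test_pts$intensity_db)
  ref <- predict(q, test_pts)$posterior[, "real"]
  expect_lt(max(abs(mine - unname(ref))), 1e-10)
})

test_that("posterior behaves at symmetric midpoints and in the limits", {
  set.seed(15)
  # symmetric classes with equal covariance: midpoint posterior is 1/2
  base <- cbind(log_pi = rnorm(50, 1.5, 0.3),
                intensity_db = rnorm(50, 0, 4))
  real <- as.data.frame(base); real$intensity_db <- real$intensity_db + 100
  false <- as.data.frame(base); false$intensity_db <- false$intensity_db + 80
  model <- fit_discrimination(real, false)
  mid <- (colMeans(real) + colMeans(false)) / 2
  expect_equal(unname(posterior_real(model, mid["log_pi"],
                                     mid["intensity_db"])),
               0.5, tolerance = 1e-9)
  # deep in the real-class region the posterior saturates at 1
  expect_gt(posterior_real(model, mean(real$log_pi), 115), 0.999)
  expect_lt(posterior_real(model, mean(false$log_pi), 65), 0.001)
})

test_that("equal-covariance p = 0.5 curve matches the linear-boundary form", {
  model <- separated_model()
  expect_equal(model$real$cov, model$false$cov)   # construction
  curve <- threshold_curve_from_model(model, p = 0.5)
  w <- solve(model$real$cov, model$real$mean - model$false$mean)
  m <- (model$real$mean + model$false$mean) / 2
  closed <- (sum(w * m) - w[1] * log10(curve$pulse_interval_ms)) / w[2]
  expect_lt(max(abs(curve$threshold_dB - closed)), 1e-6)
  # p = 0.75 sits above p = 0.5 when the real class is the louder one
  c75 <- threshold_curve_from_model(model, p = 0.75)
  expect_true(all(c75$threshold_dB > curve$threshold_dB))
})

test_that("AUR enumerates pair probabilities with ties at one half", {
  expect_equal(auc_real_vs_false(c(3, 4, 5), c(1, 2))$aur, 1)
  expect_equal(auc_real_vs_false(c(1, 2, 3), c(1, 2, 3))$aur, 0.5)
  expect_equal(auc_real_vs_false(c(1, 3), c(2, 4))$aur, 0.25)
  r <- auc_real_vs_false(rnorm(10), rnorm(20))
  expect_equal(r$n_real, 10); expect_equal(r$n_false, 20)
  expect_error(auc_real_vs_false(numeric(0), 1), "non-empty")
})

test_that("pairwise AUR equals the rank-statistic formulation", {
  set.seed(16)
  for (i in 1:50) {
    r <- sample(0:20, sample(3:15, 1), replace = TRUE)  # integer ties
    f <- sample(0:20, sample(3:15, 1), replace = TRUE)
    aur <- auc_real_vs_false(r, f)$aur
    rk <- rank(c(r, f))
    U <- sum(rk[seq_along(r)]) - length(r) * (length(r) + 1) / 2
    expect_equal(aur, U / (length(r) * length(f)), tolerance = 0)
  }
})

test_that("separability grows with the real/false intensity offset", {
  set.seed(17)
  base <- rnorm(200, 85, 4)
  aurs <- vapply(c(0, 2, 4, 8), function(delta)
    auc_real_vs_false(rnorm(200, 85 + delta, 4), base)$aur, numeric(1))
  expect_true(all(diff(aurs) > 0))
  expect_lt(abs(aurs[1] - 0.5), 0.08)   # Monte-Carlo error at delta = 0
})

test_that("stepwise discrimination selects informative variables", {
  set.seed(18)
  n <- 40
  click <- data.frame(intensity_db = rnorm(n, 95, 2),
                      log_pi = rnorm(n, 1.4, 0.2),
                      junk = rnorm(n))
  nonclick <- data.frame(intensity_db = rnorm(n, 75, 2),
                         log_pi = rnorm(n, 1.8, 0.2),
                         junk = rnorm(n))
  res <- discriminate_passes(click, nonclick)
  expect_true("intensity_db" %in% res$selected)
  expect_false("junk" %in% res$selected)
  expect_equal(res$ppv_pct, 100)
  expect_equal(res$npv_pct, 100)
  # classification counts agree with brute-force application of the rule
  pred <- predict(res$model,
                  rbind(click, nonclick)[, res$selected, drop = FALSE])$class
  expect_equal(res$ppv_pct, 100 * mean(pred[1:n] == "click"))
  expect_equal(res$npv_pct, 100 * mean(pred[(n + 1):(2 * n)] == "nonclick"))
})

test_that("label-permuted data rarely admits any variable", {
  set.seed(19)
  pool <- data.frame(intensity_db = rnorm(60, 85, 5),
                     log_pi = rnorm(60, 1.5, 0.3))
  admitted <- vapply(1:40, function(i) {
    idx <- sample(60, 30)
    res <- suppressWarnings(discriminate_passes(pool[idx, ], pool[-idx, ]))
    length(res$selected) > 0
  }, logical(1))
  # two candidates at P-to-enter 0.05: null admission rate near 0.1
  expect_lt(mean(admitted), 0.3)
  expect_error(discriminate_passes(pool[1:3, ], pool[4:10, ]),
               "at least 5")
})
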