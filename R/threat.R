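# Decision analyses: clicking-threshold extraction and phase means,
# two-class Gaussian (quadratic discriminant) real-vs-false threat
# thresholds at posterior p, ROC/AUR separability, and clicking vs
# non-clicking pass discrimination with PPV/NPV.

PHASE_REPRESENTATIVE_PI <- list(search = c(80, 100),
                                approach = c(20, 30, 45),
                                buzz = c(4, 7))

#' Clicking-threshold curve
#'
#' An ordered mapping from pulse interval to the intensity that elicits
#' clicking, interpolated linearly in log10 pulse interval.
#'
#' @param pulse_interval_ms strictly increasing pulse intervals (ms).
#' @param threshold_dB thresholds within \[60, 130\] dB.
#' @return an object of class `threshold_curve`.
#' @export
threshold_curve <- function(pulse_interval_ms, threshold_dB) {
  stopifnot(length(pulse_interval_ms) == length(threshold_dB),
            length(pulse_interval_ms) >= 1L)
  o <- order(pulse_interval_ms)
  pulse_interval_ms <- pulse_interval_ms[o]
  threshold_dB <- threshold_dB[o]
  if (any(diff(pulse_interval_ms) <= 0))
    stop("pulse intervals must be strictly increasing")
  if (any(threshold_dB < 60 | threshold_dB > 130, na.rm = TRUE))
    stop("thresholds must lie within [60, 130] dB")
  structure(list(pulse_interval_ms = pulse_interval_ms,
                 threshold_dB = threshold_dB),
            class = "threshold_curve")
}

#' Evaluate a threshold curve at arbitrary pulse intervals
#'
#' Linear interpolation in log10 pulse interval; constant extrapolation
#' beyond the measured range.
#'
#' @param curve a [threshold_curve()].
#' @param pulse_interval_ms query pulse interval(s), ms.
#' @return threshold(s) in dB.
#' @export
threshold_at <- function(curve, pulse_interval_ms) {
  stopifnot(inherits(curve, "threshold_curve"))
  ok <- !is.na(curve$threshold_dB)
  if (sum(ok) == 1L) return(rep(curve$threshold_dB[ok],
                                length(pulse_interval_ms)))
  stats::approx(log10(curve$pulse_interval_ms[ok]), curve$threshold_dB[ok],
                xout = log10(pulse_interval_ms), rule = 2)$y
}

#' Clicking threshold from a ramp playback
#'
#' The level of the last pulse starting strictly before the first click:
#' the intensity of the playback immediately preceding the response.
#'
#' @param stimulus a [make_ramp_playback()] stimulus.
#' @param first_click_time_s time of the first click (s), or `NA` for no
#'   click.
#' @return threshold in dB, or `NA_real_` if the moth never clicked.
#' @export
extract_threshold_from_ramp <- function(stimulus, first_click_time_s) {
  stopifnot(inherits(stimulus, "ramp_stimulus"))
  if (is.na(first_click_time_s)) return(NA_real_)
  prior <- which(stimulus$pulse_times_s < first_click_time_s)
  if (!length(prior))
    stop("click precedes the first pulse of the stimulus")
  stimulus$pulse_levels_db[max(prior)]
}

#' Measure a full threshold curve with ramp playbacks
#'
#' Runs one ramp playback per supported pulse interval against a
#' simulated moth and reads each clicking threshold back out.
#'
#' @param moth a [moth_response_model()].
#' @param pulse_intervals_ms pulse intervals to test.
#' @param seed seed passed to the response simulation.
#' @return a [threshold_curve()] of measured thresholds (NA where the
#'   moth never clicked).
#' @export
measure_threshold_curve <- function(moth,
                                    pulse_intervals_ms = RAMP_PULSE_INTERVALS_MS,
                                    seed = 1L) {
  thr <- vapply(seq_along(pulse_intervals_ms), function(i) {
    stim <- make_ramp_playback(pulse_intervals_ms[i])
    ct <- simulate_moth_response(stim, moth, seed = seed + i)
    if (is.na(ct)) NA_real_ else extract_threshold_from_ramp(stim, ct)
  }, numeric(1))
  curve <- threshold_curve(pulse_intervals_ms, pmin(pmax(thr, 60), 130))
  curve$threshold_dB[is.na(thr)] <- NA_real_
  curve
}

#' Per-phase mean clicking thresholds
#'
#' Averages thresholds over the representative pulse intervals of each
#' echolocation phase (search: 80, 100 ms; approach: 20, 30, 45 ms;
#' buzz: 4, 7 ms). The transitional intervals 12 and 60 ms are excluded.
#'
#' @param curve a [threshold_curve()] containing the representative
#'   pulse intervals.
#' @return named numeric vector with elements search, approach, buzz.
#' @export
phase_mean_thresholds <- function(curve) {
  stopifnot(inherits(curve, "threshold_curve"))
  vapply(PHASE_REPRESENTATIVE_PI, function(pis) {
    idx <- match(pis, curve$pulse_interval_ms)
    if (anyNA(idx))
      stop("threshold curve is missing representative pulse interval(s): ",
           paste(pis[is.na(idx)], collapse = ", "), " ms")
    mean(curve$threshold_dB[idx])
  }, numeric(1))
}

# ---- two-class Gaussian discrimination -------------------------------------

#' Fit a two-class Gaussian (quadratic discriminant) threat model
#'
#' Models real-threat and false-threat calls as bivariate Gaussians over
#' (log10 pulse interval, intensity at the moth). Class means and
#' covariances are the sample estimates; the posterior probability that
#' a call is a real threat follows from the two-class density ratio with
#' the supplied priors.
#'
#' @param real_points,false_points matrices or data frames with columns
#'   `log_pi` (log10 pulse interval, ms) and `intensity_db`; >= 3 rows
#'   each. Use [threat_points()] to build them from raw features.
#' @param priors length-2 prior (real, false), summing to 1.
#' @return an object of class `discrimination_model`.
#' @export
fit_discrimination <- function(real_points, false_points,
                               priors = c(0.5, 0.5)) {
  as_mat <- function(x, nm) {
    x <- as.matrix(as.data.frame(x)[, c("log_pi", "intensity_db")])
    if (nrow(x) < 3L) stop(nm, " needs at least 3 points")
    x
  }
  R <- as_mat(real_points, "real_points")
  F <- as_mat(false_points, "false_points")
  stopifnot(length(priors) == 2L, abs(sum(priors) - 1) < 1e-9,
            all(priors > 0))
  comp <- function(X) {
    S <- stats::cov(X)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev))
      stop("singular class covariance; add points or regularize features")
    list(mean = colMeans(X), cov = S)
  }
  structure(list(real = comp(R), false = comp(F), priors = priors,
                 n = c(real = nrow(R), false = nrow(F))),
            class = "discrimination_model")
}

#' Feature points for threat discrimination
#'
#' @param pulse_interval_ms pulse intervals (ms, > 0).
#' @param intensity_db levels at the moth (dB).
#' @return data frame with columns `log_pi`, `intensity_db`.
#' @export
threat_points <- function(pulse_interval_ms, intensity_db) {
  stopifnot(all(pulse_interval_ms > 0, na.rm = TRUE))
  data.frame(log_pi = log10(pulse_interval_ms), intensity_db = intensity_db)
}

# log bivariate normal density
.ldmvnorm <- function(x, mean, cov) {
  d <- x - mean
  L <- chol(cov)
  z <- backsolve(L, d, transpose = TRUE)
  -log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

#' Posterior probability of a real threat
#'
#' @param model a [fit_discrimination()] model.
#' @param log_pi log10 pulse interval(s) (ms).
#' @param intensity_db intensity(ies) at the moth (dB).
#' @return posterior P(real | x) in \[0, 1\], vectorized.
#' @export
posterior_real <- function(model, log_pi, intensity_db) {
  stopifnot(inherits(model, "discrimination_model"))
  mapply(function(lp, ix) {
    x <- c(lp, ix)
    lr <- .ldmvnorm(x, model$real$mean, model$real$cov) +
      log(model$priors[1])
    lf <- .ldmvnorm(x, model$false$mean, model$false$cov) +
      log(model$priors[2])
    1 / (1 + exp(lf - lr))
  }, log_pi, intensity_db)
}

#' Iso-posterior threshold curve from a discrimination model
#'
#' For each pulse interval on a grid, the lowest intensity at which the
#' posterior probability of a real threat reaches `p`, found by a
#' bracketed root search over \[60, 130\] dB (the posterior is generally
#' increasing in intensity when the real class sits at higher
#' intensities; where several crossings exist the lowest is returned and
#' flagged). `NA` where no crossing exists.
#'
#' @param model a [fit_discrimination()] model.
#' @param p posterior level in (0, 1), e.g. 0.5 or 0.75.
#' @param pi_grid_ms pulse-interval grid (ms).
#' @param intensity_range_db search bracket in dB.
#' @return a [threshold_curve()]; attribute `multiple_crossings` flags
#'   grid points with a non-monotone posterior.
#' @export
threshold_curve_from_model <- function(model, p = 0.5,
                                       pi_grid_ms = RAMP_PULSE_INTERVALS_MS,
                                       intensity_range_db = c(60, 130)) {
  stopifnot(inherits(model, "discrimination_model"), p > 0, p < 1)
  pi_grid_ms <- sort(pi_grid_ms)
  lo <- intensity_range_db[1]; hi <- intensity_range_db[2]
  grid_I <- seq(lo, hi, by = 0.25)
  thr <- rep(NA_real_, length(pi_grid_ms))
  multi <- logical(length(pi_grid_ms))
  for (i in seq_along(pi_grid_ms)) {
    lp <- log10(pi_grid_ms[i])
    post <- posterior_real(model, rep(lp, length(grid_I)), grid_I) - p
    sgn <- sign(post)
    cross <- which(diff(sgn >= 0) != 0)
    if (post[1] >= 0) { thr[i] <- lo; next }  # already above p at 60 dB
    if (!length(cross)) next                   # no crossing in range
    multi[i] <- length(cross) > 1L
    j <- cross[1]
    thr[i] <- stats::uniroot(function(I)
      posterior_real(model, lp, I) - p,
      lower = grid_I[j], upper = grid_I[j + 1L], tol = 1e-9)$root
  }
  if (any(multi))
    warning("non-monotone posterior in intensity at some pulse intervals; ",
            "lowest crossing returned")
  curve <- threshold_curve(pi_grid_ms, thr)
  attr(curve, "multiple_crossings") <- multi
  curve
}

#' Area under the ROC curve by pairwise enumeration
#'
#' The probability that a randomly chosen call from the real-threat group
#' has a higher intensity than a randomly chosen call from the
#' false-threat group: the fraction of (real, false) pairs with
#' real > false, ties counted one half.
#'
#' @param real_intensities,false_intensities non-empty numeric vectors.
#' @return list of class `roc_result`: `aur`, `n_real`, `n_false`.
#' @export
auc_real_vs_false <- function(real_intensities, false_intensities) {
  r <- real_intensities[!is.na(real_intensities)]
  f <- false_intensities[!is.na(false_intensities)]
  if (!length(r) || !length(f))
    stop("both intensity groups must be non-empty")
  cmp <- outer(r, f, FUN = function(a, b)
    (a > b) + 0.5 * (a == b))
  structure(list(aur = mean(cmp), n_real = length(r), n_false = length(f)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUR = %.3f (n_real = %d, n_false = %d)\n",
              x$aur, x$n_real, x$n_false))
  invisible(x)
}

# ---- stepwise discriminant classification of passes ------------------------

# partial F for adding one variable to a 2-group discriminant model,
# via the Wilks-lambda ratio (for 2 groups, F has (1, n - p - 2) df)
.partial_F <- function(groups, X_in, x_new) {
  n <- length(groups)
  wilks <- function(X) {
    if (is.null(X) || ncol(as.matrix(X)) == 0L) return(1)
    X <- as.matrix(X)
    Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
    W <- matrix(0, ncol(X), ncol(X))
    for (g in unique(groups)) {
      Xg <- X[groups == g, , drop = FALSE]
      W <- W + crossprod(scale(Xg, center = TRUE, scale = FALSE))
    }
    det(W) / det(Tm)
  }
  p <- if (is.null(X_in)) 0L else ncol(as.matrix(X_in))
  L_in <- wilks(X_in)
  L_full <- wilks(cbind(X_in, x_new))
  df2 <- n - p - 2L
  Fval <- df2 * (L_in / L_full - 1)
  list(F = Fval, p_value = stats::pf(Fval, 1, df2, lower.tail = FALSE))
}

#' Discriminate clicking from non-clicking bat passes
#'
#' Forward-stepwise discriminant analysis over candidate acoustic and
#' flight variables: at each step the variable with the smallest
#' partial-F p-value below `p_to_enter` joins the model; selection stops
#' when none qualifies. The final linear discriminant (equal priors)
#' classifies every event, and performance is summarized as the percent
#' of clicking events classified as clicking (PPV, as used here) and the
#' percent of non-clicking events classified as non-clicking (NPV) --
#' sensitivity and specificity in standard nomenclature.
#'
#' @param click_features,nonclick_features data frames with the candidate
#'   variables as columns; >= 5 rows each.
#' @param candidate_vars variables to consider (default: all shared
#'   columns).
#' @param p_to_enter entry threshold for the stepwise partial-F test.
#' @return list of class `pass_discrimination`: `selected` (character),
#'   `model` (the `MASS::lda` fit, or NULL if no variable entered),
#'   `ppv_pct`, `npv_pct`, `classified` (per-event predicted class).
#' @export
discriminate_passes <- function(click_features, nonclick_features,
                                candidate_vars = NULL, p_to_enter = 0.05) {
  click_features <- as.data.frame(click_features)
  nonclick_features <- as.data.frame(nonclick_features)
  if (nrow(click_features) < 5L || nrow(nonclick_features) < 5L)
    stop("need at least 5 events per group")
  if (is.null(candidate_vars))
    candidate_vars <- intersect(names(click_features),
                                names(nonclick_features))
  stopifnot(length(candidate_vars) >= 1L)
  X <- rbind(click_features[, candidate_vars, drop = FALSE],
             nonclick_features[, candidate_vars, drop = FALSE])
  grp <- factor(rep(c("click", "nonclick"),
                    c(nrow(click_features), nrow(nonclick_features))))
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; grp <- droplevels(grp[keep])

  selected <- character(0)
  remaining <- candidate_vars
  repeat {
    if (!length(remaining)) break
    Xin <- if (length(selected)) X[, selected, drop = FALSE] else NULL
    tests <- lapply(remaining, function(v)
      .partial_F(grp, Xin, X[[v]]))
    pvals <- vapply(tests, `[[`, numeric(1), "p_value")
    best <- which.min(pvals)
    if (!is.finite(pvals[best]) || pvals[best] >= p_to_enter) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  if (!length(selected)) {
    warning("no variable passed the entry criterion; intercept-only model")
    maj <- names(which.max(table(grp)))
    pred <- factor(rep(maj, nrow(X)), levels = levels(grp))
    model <- NULL
  } else {
    model <- MASS::lda(X[, selected, drop = FALSE], grouping = grp,
                       prior = c(0.5, 0.5))
    pred <- stats::predict(model, X[, selected, drop = FALSE])$class
  }
  ppv <- 100 * mean(pred[grp == "click"] == "click")
  npv <- 100 * mean(pred[grp == "nonclick"] == "nonclick")
  structure(list(selected = selected, model = model,
                 ppv_pct = ppv, npv_pct = npv,
                 classified = pred, group = grp),
            class = "pass_discrimination")
}

#' @export
print.pass_discrimination <- function(x, ...) {
  cat(sprintf("<pass_discrimination> variables: %s | PPV = %.1f%%, NPV = %.1f%%\n",
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)", x$ppv_pct, x$npv_pct))
  invisible(x)
}
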