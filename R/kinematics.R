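# 3-D flight kinematics: quintic smoothing-spline track fits, flight and
# approach-angle vectors, and the videogrammetry wand-error check.

#' Raw 3-D track
#'
#' @param times sample times in seconds, strictly increasing (nominally
#'   60 frames/s video).
#' @param positions numeric matrix, one row per sample, columns x/y/z in
#'   meters (right-handed, z up).
#' @return an object of class `raw_track`.
#' @export
raw_track <- function(times, positions) {
  times <- as.numeric(times)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("positions must have 3 columns (x, y, z in meters)")
  if (nrow(positions) != length(times))
    stop("times and positions must have the same number of samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  colnames(positions) <- c("x", "y", "z")
  structure(list(times = times, positions = positions), class = "raw_track")
}

# ---- quintic smoothing spline ----------------------------------------------
# Penalized regression on a degree-5 B-spline basis with knots tied to the
# data, minimizing sum (y - f)^2 + lambda * int f'''(t)^2 dt. The penalty
# null space is the quadratics; lambda = 0 interpolates (the basis has as
# many functions as data points and spans all quintic polynomials).

.quintic_basis_knots <- function(t) {
  n <- length(t)
  if (n < 6L) stop("at least 6 samples are required for a quintic spline fit")
  # n - 6 interior knots -> exactly n basis functions of order 6
  interior <- if (n > 6L) t[seq(4L, n - 3L)] else numeric(0)
  c(rep(t[1], 6), interior, rep(t[n], 6))
}

# exact penalty matrix int B_i''' B_j''' dt by Gauss-Legendre (3-pt) per
# knot span: third derivatives are piecewise quadratic, products quartic.
.quintic_penalty <- function(knots) {
  k <- length(knots) - 12L + 6L  # number of basis functions
  spans <- unique(knots)
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5 / 9, 8 / 9, 5 / 9)
  P <- matrix(0, k, k)
  for (i in seq_len(length(spans) - 1L)) {
    a <- spans[i]; b <- spans[i + 1L]
    if (b <= a) next
    xm <- (a + b) / 2 + (b - a) / 2 * gx
    B3 <- splines::splineDesign(knots, xm, ord = 6L, derivs = 3L)
    P <- P + crossprod(B3 * sqrt(gw * (b - a) / 2))
  }
  P
}

#' Fit a quintic smoothing spline to a 3-D track
#'
#' Each coordinate is fit independently with a penalized degree-5 B-spline
#' whose roughness penalty is the integrated squared third derivative, the
#' classical quintic smoothing spline. `smoothing = 0` interpolates the
#' samples exactly (and reproduces any quintic polynomial trajectory);
#' larger values shrink toward a quadratic in time. The default selects
#' the penalty weight per coordinate by generalized cross-validation.
#'
#' @param raw a [raw_track()] (>= 6 samples).
#' @param smoothing penalty weight `lambda` (>= 0), or `"gcv"` (default)
#'   to select it by generalized cross-validation.
#' @return an object of class `smooth_track`, evaluable by
#'   [track_position()] and [track_velocity()].
#' @export
fit_smooth_track <- function(raw, smoothing = "gcv") {
  stopifnot(inherits(raw, "raw_track"))
  t <- raw$times
  knots <- .quintic_basis_knots(t)
  B <- splines::splineDesign(knots, t, ord = 6L)
  P <- .quintic_penalty(knots)
  BtB <- crossprod(B)
  fit_one <- function(y, lambda) {
    coefs <- solve(BtB + lambda * P, crossprod(B, y))
    as.numeric(coefs)
  }
  gcv_one <- function(y) {
    score <- function(loglam) {
      lambda <- exp(loglam)
      A <- solve(BtB + lambda * P, t(B))  # k x n
      H_diag_sum <- sum(B * t(A))         # trace of hat matrix
      resid <- y - B %*% (A %*% y)
      n <- length(y)
      n * sum(resid^2) / (n - H_diag_sum)^2
    }
    opt <- stats::optimize(score, interval = log(c(1e-12, 1e4)))
    exp(opt$minimum)
  }
  coords <- lapply(1:3, function(j) {
    y <- raw$positions[, j]
    lambda <- if (identical(smoothing, "gcv")) gcv_one(y) else {
      stopifnot(is.numeric(smoothing), smoothing >= 0)
      smoothing
    }
    list(coef = fit_one(y, lambda), lambda = lambda)
  })
  structure(list(knots = knots, coords = coords,
                 range = range(t), raw = raw),
            class = "smooth_track")
}

.track_eval <- function(track, t, deriv = 0L) {
  stopifnot(inherits(track, "smooth_track"))
  if (any(t < track$range[1] - 1e-12) || any(t > track$range[2] + 1e-12))
    stop("evaluation time outside the fitted track range")
  t <- pmin(pmax(t, track$range[1]), track$range[2])
  B <- splines::splineDesign(track$knots, t, ord = 6L, derivs = deriv)
  out <- vapply(track$coords, function(cc) as.numeric(B %*% cc$coef),
                numeric(length(t)))
  if (length(t) == 1L) matrix(out, 1L, 3L,
                              dimnames = list(NULL, c("x", "y", "z")))
  else `colnames<-`(out, c("x", "y", "z"))
}

#' Evaluate a fitted track
#'
#' @param track a `smooth_track` from [fit_smooth_track()].
#' @param t time(s) in seconds within the fitted range.
#' @return matrix with columns x, y, z: position in meters
#'   ([track_position()]) or velocity in m/s ([track_velocity()]).
#' @export
track_position <- function(track, t) .track_eval(track, t, 0L)

#' @rdname track_position
#' @export
track_velocity <- function(track, t) .track_eval(track, t, 1L)

#' Approach angle between flight vector and bat-to-target vector
#'
#' The angle phi between the bat's instantaneous velocity and the vector
#' from the bat to a target position: 0 when flying directly at the
#' target, 180 when flying directly away. Reported `NA` (with a warning)
#' when the bat's speed is below `min_speed` m/s, where the flight
#' direction is numerically meaningless.
#'
#' @param bat a `smooth_track` for the bat.
#' @param target_position numeric 3-vector (m).
#' @param t evaluation time(s) in seconds.
#' @param min_speed minimum speed (m/s) for a defined angle.
#' @return angle(s) in degrees within \[0, 180\], `NA` where undefined.
#' @export
approach_angle <- function(bat, target_position, t, min_speed = 0.05) {
  stopifnot(length(target_position) == 3L)
  v <- track_velocity(bat, t)
  p <- track_position(bat, t)
  d <- sweep(-p, 2, -as.numeric(target_position))  # target - position
  speed <- sqrt(rowSums(v^2))
  dn <- sqrt(rowSums(d^2))
  ang <- rep(NA_real_, length(t))
  ok <- speed >= min_speed & dn > 0
  if (any(!ok)) warning("approach angle undefined at near-zero speed; NA returned")
  cosang <- rowSums(v[ok, , drop = FALSE] * d[ok, , drop = FALSE]) /
    (speed[ok] * dn[ok])
  ang[ok] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ang
}

#' Calibration wand error
#'
#' Accuracy check for 3-D videogrammetry reconstructions: a wand with two
#' markers at known separation is moved through the calibrated volume and
#' the reconstructed inter-marker distances are compared with truth.
#'
#' @param measured_cm reconstructed inter-marker distances per frame (cm).
#' @param true_cm the known marker separation (cm, > 0).
#' @return list with `mean_abs_error_cm` and `percent_error`
#'   (100 * mean absolute error / true separation).
#' @export
wand_error <- function(measured_cm, true_cm) {
  if (!length(measured_cm)) stop("measured_cm must be non-empty")
  if (!is.numeric(true_cm) || length(true_cm) != 1L || true_cm <= 0)
    stop("true_cm must be a single positive separation in cm")
  if (any(measured_cm <= 0)) stop("measured distances must be positive")
  mae <- mean(abs(measured_cm - true_cm))
  list(mean_abs_error_cm = mae, percent_error = 100 * mae / true_cm)
}
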