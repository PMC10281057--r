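#' Configuration for the kinematic biomarkers
#'
#' Bundles every tunable constant used to turn a regularized wrist-IMU
#' stream into the two drumming biomarkers.
#'
#' @param radius_m radius of gyration in metres converting angular to linear
#'   wrist velocity; default 0.223 m, the mean adult forearm length.
#' @param rest_threshold_ms2 linear (gravity-removed) acceleration magnitude
#'   at or below which a sample counts as rest and is excluded from the
#'   velocity average; default 0.1 m/s\eqn{^2}.
#' @param window_s elevation window length in seconds; the elevation metric
#'   averages the per-window maxima; default 1 s.
#' @param gravity_ms2 standard gravity; default 9.80665 m/s\eqn{^2}.
#' @param gravity_tau_s time constant (s) of the exponential low-pass that
#'   feeds accelerometer information into the gravity-direction estimate;
#'   default 1 s.
#' @param orientation_method `"complementary"` (default) fuses the gyroscope
#'   with the low-passed accelerometer; `"accel"` uses the low-passed
#'   accelerometer alone (adequate only for quasi-static motion).
#' @param lever_arm_comp logical; subtract the rigid-rotation (tangential +
#'   centripetal) acceleration predicted by the gyroscope at the sensor
#'   position `-radius_m` along the forearm axis before using the
#'   accelerometer as a gravity reference.  Default `TRUE`.
#' @param min_accel_ms2 accelerometer-magnitude floor (m/s\eqn{^2}) below
#'   which the gravity reference is considered degenerate and the sample is
#'   flagged invalid; default 0.5.
#' @return an object of class `kinematic_config`.
#' @export
kinematic_config <- function(radius_m = 0.223, rest_threshold_ms2 = 0.1,
                             window_s = 1.0, gravity_ms2 = 9.80665,
                             gravity_tau_s = 1.0,
                             orientation_method = c("complementary", "accel"),
                             lever_arm_comp = TRUE, min_accel_ms2 = 0.5) {
  orientation_method <- match.arg(orientation_method)
  num <- c(radius_m = radius_m, rest_threshold_ms2 = rest_threshold_ms2,
           window_s = window_s, gravity_ms2 = gravity_ms2,
           gravity_tau_s = gravity_tau_s, min_accel_ms2 = min_accel_ms2)
  if (!all(is.finite(num)) || any(num <= 0))
    stop("all kinematic_config numeric fields must be strictly positive")
  structure(list(radius_m = radius_m, rest_threshold_ms2 = rest_threshold_ms2,
                 window_s = window_s, gravity_ms2 = gravity_ms2,
                 gravity_tau_s = gravity_tau_s,
                 orientation_method = orientation_method,
                 lever_arm_comp = isTRUE(lever_arm_comp),
                 min_accel_ms2 = min_accel_ms2),
            class = "kinematic_config")
}

#' @export
print.kinematic_config <- function(x, ...) {
  cat("<kinematic_config>\n")
  cat(sprintf("  radius %g m | rest threshold %g m/s^2 | window %g s\n",
              x$radius_m, x$rest_threshold_ms2, x$window_s))
  cat(sprintf("  gravity %g m/s^2, tau %g s | orientation: %s%s\n",
              x$gravity_ms2, x$gravity_tau_s, x$orientation_method,
              if (x$lever_arm_comp) " + lever-arm compensation" else ""))
  invisible(x)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rotate_about <- function(v, axis, angle) {
  # Rodrigues rotation of a single 3-vector
  ct <- cos(angle); st <- sin(angle)
  kv <- c(axis[2] * v[3] - axis[3] * v[2],
          axis[3] * v[1] - axis[1] * v[3],
          axis[1] * v[2] - axis[2] * v[1])
  v * ct + kv * st + axis * sum(axis * v) * (1 - ct)
}

check_regularized <- function(stream) {
  if (!inherits(stream, "imu_stream")) stop("expected an imu_stream")
  if (!stream$regularized)
    stop("stream must be regularized first (see regularize())")
  if (nrow(stream$data) < 2L) stop("insufficient data: need at least 2 samples")
}

#' Estimate the per-sample gravity direction
#'
#' Tracks the unit "up" direction (the reaction to gravity reported by an
#' accelerometer at rest) in the device frame.  The default complementary
#' scheme propagates the previous estimate through the gyroscope rotation
#' over each sample period (Simpson-quadrature angular increment) and then
#' nudges it toward the accelerometer direction with gain
#' `dt / (gravity_tau_s + dt)`, i.e. an exponential low-pass of the
#' accelerometer with the configured time constant.  When
#' `lever_arm_comp` is on, the rigid-rotation acceleration
#' \eqn{\dot\omega \times p + \omega \times (\omega \times p)} predicted at
#' the sensor position \eqn{p = (0, 0, -r)} (wrist at radius r from the
#' elbow along the forearm axis) is removed from the accelerometer signal
#' before it is used as a gravity reference, which suppresses the swing's
#' tangential and centripetal contamination.  The `"accel"` method is the
#' plain low-pass with no gyro input.
#'
#' Samples where the (compensated, low-passed) accelerometer magnitude
#' falls below `min_accel_ms2` carry no usable gravity reference and are
#' flagged invalid.
#'
#' @param stream a regularized [imu_stream()].
#' @param config a [kinematic_config()].
#' @return an `orientation_series`: data.frame with columns `t`, `vx`, `vy`,
#'   `vz` (unit vector V_t, the estimated up direction in the device frame)
#'   and `valid`.
#' @export
estimate_gravity <- function(stream, config = kinematic_config()) {
  check_regularized(stream)
  stopifnot(inherits(config, "kinematic_config"))
  d <- stream$data
  n <- nrow(d)
  dt <- 1 / stream$nominal_rate
  accel <- as.matrix(d[, c("ax", "ay", "az")])
  gyro <- as.matrix(d[, c("gx", "gy", "gz")])

  ac <- accel
  if (config$lever_arm_comp && config$orientation_method == "complementary") {
    # central-difference angular acceleration (one-sided at the ends)
    dom <- rbind(gyro[2, ] - gyro[1, ],
                 gyro[3:n, , drop = FALSE] - gyro[1:(n - 2), , drop = FALSE],
                 gyro[n, ] - gyro[n - 1, ]) /
      c(dt, rep(2 * dt, n - 2), dt)
    p <- matrix(rep(c(0, 0, -config$radius_m), each = n), n)
    ac <- accel - (cross3(dom, p) + cross3(gyro, cross3(gyro, p)))
  }
  amag <- sqrt(rowSums(ac^2))

  alpha <- dt / (config$gravity_tau_s + dt)
  V <- matrix(NA_real_, n, 3)
  lp_mag <- numeric(n)

  if (config$orientation_method == "accel") {
    G <- ac
    for (i in 2:n) G[i, ] <- G[i - 1, ] + alpha * (ac[i, ] - G[i - 1, ])
    lp_mag <- sqrt(rowSums(G^2))
    valid <- lp_mag >= config$min_accel_ms2
    V[valid, ] <- G[valid, , drop = FALSE] / lp_mag[valid]
  } else {
    # cubic-interpolated midpoint -> Simpson quadrature of the angular
    # increment over each sample period; the trapezoid alone attenuates
    # step angles by (wh/2)cot(wh/2) at swing frequencies
    im2 <- pmax(seq_len(n) - 2L, 1L)
    ip1 <- pmin(seq_len(n) + 1L, n)
    wmid <- (-gyro[im2, , drop = FALSE] +
               9 * gyro[pmax(seq_len(n) - 1L, 1L), , drop = FALSE] +
               9 * gyro - gyro[ip1, , drop = FALSE]) / 16
    lp_mag[1] <- amag[1]
    v <- if (amag[1] >= config$min_accel_ms2) ac[1, ] / amag[1] else c(0, 0, 1)
    V[1, ] <- v
    for (i in 2:n) {
      wstep <- (gyro[i - 1, ] + 4 * wmid[i, ] + gyro[i, ]) / 6
      nw <- sqrt(sum(wstep^2))
      # a world-fixed vector appears to rotate by -omega in the device frame
      if (nw > 0) v <- rotate_about(v, wstep / nw, -nw * dt)
      lp_mag[i] <- lp_mag[i - 1] + alpha * (amag[i] - lp_mag[i - 1])
      if (amag[i] >= config$min_accel_ms2)
        v <- (1 - alpha) * v + alpha * ac[i, ] / amag[i]
      nv <- sqrt(sum(v^2))
      if (nv > 0) v <- v / nv
      V[i, ] <- v
    }
    valid <- lp_mag >= config$min_accel_ms2
  }
  if (!any(valid))
    stop("degenerate signal: no sample carries a usable gravity reference")
  structure(data.frame(t = d$t, vx = V[, 1], vy = V[, 2], vz = V[, 3],
                       valid = valid),
            class = c("orientation_series", "data.frame"))
}

#' Flag rest samples by linear-acceleration magnitude
#'
#' Samples whose gravity-removed acceleration magnitude
#' \eqn{\lVert a - g\,\hat g_t\rVert} is at or below the configured
#' threshold (default 0.1 m/s\eqn{^2}) are classified as non-exercise time
#' and excluded from the velocity average.  The threshold applies to linear
#' acceleration because the raw magnitude is ~9.8 m/s\eqn{^2} at rest,
#' where a 0.1 m/s\eqn{^2} cutoff would be meaningless.
#'
#' @param stream a regularized [imu_stream()].
#' @param config a [kinematic_config()].
#' @param orientation optional precomputed [estimate_gravity()] result.
#' @return list with `stream` (rest samples removed), `keep` (logical mask
#'   on the input grid) and `n_removed`.
#' @export
rest_filter <- function(stream, config = kinematic_config(), orientation = NULL) {
  check_regularized(stream)
  if (is.null(orientation)) orientation <- estimate_gravity(stream, config)
  d <- stream$data
  accel <- as.matrix(d[, c("ax", "ay", "az")])
  V <- as.matrix(orientation[, c("vx", "vy", "vz")])
  lin <- accel - config$gravity_ms2 * V
  linmag <- sqrt(rowSums(lin^2))
  keep <- linmag > config$rest_threshold_ms2 & orientation$valid
  keep[is.na(keep)] <- FALSE
  filtered <- d[keep, , drop = FALSE]
  out <- if (sum(keep) >= 1L) {
    s <- stream
    s$data <- filtered
    s
  } else {
    NULL
  }
  list(stream = out, keep = keep, n_removed = sum(!keep))
}

#' Average arm velocity (m/s)
#'
#' The wrist-velocity biomarker: the angle between successive
#' gravity-referenced unit vectors, divided by the sample period and scaled
#' by the radius of gyration,
#' \eqn{\bar v = \mathrm{mean}\,[\arccos(V_t \cdot V_{t-\Delta t}) / \Delta t] \times r}.
#' Only consecutive grid pairs in which both samples survive the rest
#' filter (and are valid) contribute.  Dot products are clamped to
#' \eqn{[-1, 1]} before `acos` for floating-point safety.
#'
#' @param stream a regularized [imu_stream()].
#' @param config a [kinematic_config()].
#' @param orientation optional precomputed [estimate_gravity()] result.
#' @return average arm velocity in m/s.
#' @export
average_arm_velocity <- function(stream, config = kinematic_config(),
                                 orientation = NULL) {
  check_regularized(stream)
  if (is.null(orientation)) orientation <- estimate_gravity(stream, config)
  rf <- rest_filter(stream, config, orientation)
  keep <- rf$keep
  if (sum(keep) < 2L)
    stop("insufficient data: fewer than 2 non-rest samples")
  n <- length(keep)
  pair <- keep[-n] & keep[-1]
  if (!any(pair))
    stop("insufficient data: no consecutive non-rest sample pair")
  V <- as.matrix(orientation[, c("vx", "vy", "vz")])
  dots <- rowSums(V[-n, , drop = FALSE] * V[-1, , drop = FALSE])
  dtheta <- acos(pmax(-1, pmin(1, dots)))
  dt <- 1 / stream$nominal_rate
  mean(dtheta[pair]) / dt * config$radius_m
}

#' Average arm elevation angle (degrees)
#'
#' The posture biomarker: per-sample elevation
#' \eqn{\theta_z = \arcsin(V_t^{(z)})}, the angle of the
#' forearm-longitudinal device z-axis above horizontal (positive when the
#' forearm points upward; negative values are legal).  The stream is cut
#' into consecutive non-overlapping windows of `window_s` anchored at the
#' stream start (a trailing partial window is discarded); the metric is the
#' mean over windows of the within-window maximum elevation.
#'
#' @param stream a regularized [imu_stream()].
#' @param config a [kinematic_config()].
#' @param orientation optional precomputed [estimate_gravity()] result.
#' @return average elevation angle in degrees, in \eqn{[-90, 90]}.
#' @export
average_elevation_angle <- function(stream, config = kinematic_config(),
                                    orientation = NULL) {
  check_regularized(stream)
  if (is.null(orientation)) orientation <- estimate_gravity(stream, config)
  wlen <- round(config$window_s * stream$nominal_rate)
  if (wlen < 1L) stop("window_s shorter than one sample period")
  n <- nrow(orientation)
  n_win <- n %/% wlen
  if (n_win < 1L)
    stop("insufficient data: no complete elevation window")
  elev <- asin(pmax(-1, pmin(1, orientation$vz))) * 180 / pi
  elev[!orientation$valid] <- NA_real_
  idx <- rep(seq_len(n_win), each = wlen)
  wmax <- tapply(elev[seq_len(n_win * wlen)], idx, max, na.rm = TRUE)
  wmax[!is.finite(wmax)] <- NA_real_
  if (all(is.na(wmax)))
    stop("insufficient data: no window contains a valid sample")
  mean(wmax, na.rm = TRUE)
}

#' Summarize both drumming biomarkers for one stream
#'
#' Computes average arm velocity and average elevation angle on a shared
#' gravity estimate, together with quality-control counts.  An all-rest
#' stream is legal: the velocity is reported as `NA` (the elevation is
#' still computable from a static posture).
#'
#' @param stream a regularized [imu_stream()] (a non-regularized stream is
#'   regularized on the fly).
#' @param config a [kinematic_config()].
#' @return a `kinematic_summary`: one-row data.frame with columns
#'   `subject_id`, `avg_velocity_ms`, `avg_elevation_deg`,
#'   `n_samples_total`, `n_samples_rest_removed`, `n_windows`.
#' @export
summarize_kinematics <- function(stream, config = kinematic_config()) {
  if (!stream$regularized) stream <- regularize(stream)
  orientation <- estimate_gravity(stream, config)
  rf <- rest_filter(stream, config, orientation)
  vel <- tryCatch(average_arm_velocity(stream, config, orientation),
                  error = function(e) NA_real_)
  elev <- average_elevation_angle(stream, config, orientation)
  wlen <- round(config$window_s * stream$nominal_rate)
  out <- data.frame(subject_id = stream$subject_id,
                    avg_velocity_ms = vel,
                    avg_elevation_deg = elev,
                    n_samples_total = nrow(stream$data),
                    n_samples_rest_removed = rf$n_removed,
                    n_windows = nrow(stream$data) %/% wlen,
                    stringsAsFactors = FALSE)
  class(out) <- c("kinematic_summary", "data.frame")
  out
}
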