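#' Parameters of the synthetic drumming-motion simulator
#'
#' The simulator emulates the repetitive forearm swing of seated drumming
#' as a single-axis rotation about the elbow: elevation
#' \eqn{\phi(t) = \phi_0 + A \sin(2\pi f t)}, flat at \eqn{\phi_0} during
#' rest segments.  Rest entries and exits are smoothed over a short
#' raised-cosine ramp so the trajectory (and hence the simulated gyro and
#' accelerometer) stays differentiable — a physical device cannot change
#' posture discontinuously.
#'
#' Defaults describe a typical session: a forearm held about 15 degrees
#' above horizontal swinging \eqn{\pm}10 degrees at 1.5 strikes/s for 60 s,
#' sampled at 20 Hz, with consumer-MEMS noise levels (accelerometer ~0.01
#' m/s\eqn{^2}, gyro ~0.005 rad/s RMS at this bandwidth).
#'
#' @param elevation_offset_deg mean elevation \eqn{\phi_0} (degrees).
#' @param swing_amplitude_deg swing amplitude A (degrees);
#'   \eqn{|\phi_0| + A \le 90}.
#' @param swing_freq_hz swing frequency f (Hz), > 0.
#' @param duration_s stream duration (s).
#' @param rate_hz sampling rate (Hz), default 20.
#' @param accel_noise_sd_ms2 accelerometer noise SD per axis.
#' @param gyro_noise_sd_rads gyroscope noise SD per axis (rad/s).
#' @param rest_segments list of `c(start_s, end_s)` rest intervals, within
#'   the duration and non-overlapping.
#' @param ramp_s rest entry/exit ramp length (s), default 0.25.
#' @param seed integer seed.
#' @return an object of class `synthetic_motion_params`.
#' @export
motion_params <- function(elevation_offset_deg = 15, swing_amplitude_deg = 10,
                          swing_freq_hz = 1.5, duration_s = 60, rate_hz = 20,
                          accel_noise_sd_ms2 = 0.01,
                          gyro_noise_sd_rads = 0.005,
                          rest_segments = list(), ramp_s = 0.25, seed = 1) {
  if (abs(elevation_offset_deg) + swing_amplitude_deg > 90)
    stop("|elevation offset| + amplitude must not exceed 90 degrees")
  if (swing_freq_hz <= 0) stop("swing frequency must be positive")
  if (duration_s <= 0 || rate_hz <= 0) stop("duration and rate must be positive")
  if (swing_amplitude_deg < 0 || accel_noise_sd_ms2 < 0 || gyro_noise_sd_rads < 0)
    stop("amplitude and noise SDs must be non-negative")
  if (length(rest_segments) > 0) {
    seg <- do.call(rbind, rest_segments)
    if (ncol(seg) != 2 || any(seg[, 1] >= seg[, 2]))
      stop("rest segments must be c(start, end) with start < end")
    if (any(seg < 0) || any(seg > duration_s))
      stop("rest segments must lie within the stream duration")
    o <- order(seg[, 1])
    if (any(seg[o, 1][-1] < seg[o, 2][-nrow(seg)]))
      stop("rest segments must not overlap")
  }
  structure(list(elevation_offset_deg = elevation_offset_deg,
                 swing_amplitude_deg = swing_amplitude_deg,
                 swing_freq_hz = swing_freq_hz, duration_s = duration_s,
                 rate_hz = rate_hz, accel_noise_sd_ms2 = accel_noise_sd_ms2,
                 gyro_noise_sd_rads = gyro_noise_sd_rads,
                 rest_segments = rest_segments, ramp_s = ramp_s, seed = seed),
            class = "synthetic_motion_params")
}

# Analytic trajectory: elevation (rad) and its first two derivatives at
# times t, including the smoothed rest blend w(t) in [0, 1].
motion_trajectory <- function(params, t) {
  w <- rep(1, length(t)); wd <- rep(0, length(t)); wdd <- rep(0, length(t))
  ramp <- params$ramp_s
  for (seg in params$rest_segments) {
    s <- seg[1]; e <- seg[2]
    rlen <- min(ramp, (e - s) / 2)
    inside <- t >= s & t < e
    ws <- rep(1, length(t))
    wds <- rep(0, length(t)); wdds <- rep(0, length(t))
    ws[inside] <- 0
    if (rlen > 0) {
      i1 <- t >= s & t < s + rlen
      u <- (t[i1] - s) / rlen
      ws[i1] <- 0.5 * (1 + cos(pi * u))
      wds[i1] <- -0.5 * pi * sin(pi * u) / rlen
      wdds[i1] <- -0.5 * pi^2 * cos(pi * u) / rlen^2
      i2 <- t >= e - rlen & t < e
      u <- (t[i2] - (e - rlen)) / rlen
      ws[i2] <- 0.5 * (1 - cos(pi * u))
      wds[i2] <- 0.5 * pi * sin(pi * u) / rlen
      wdds[i2] <- 0.5 * pi^2 * cos(pi * u) / rlen^2
    }
    # product rule for the accumulated blend (segments are disjoint, so
    # the cross terms vanish except inside the current segment)
    wdd_new <- wdd * ws + 2 * wd * wds + w * wdds
    wd_new <- wd * ws + w * wds
    w <- w * ws
    wd <- wd_new
    wdd <- wdd_new
  }
  A <- params$swing_amplitude_deg * pi / 180
  phi0 <- params$elevation_offset_deg * pi / 180
  om <- 2 * pi * params$swing_freq_hz
  s_ <- sin(om * t); c_ <- cos(om * t)
  phi <- phi0 + w * A * s_
  phid <- wd * A * s_ + w * A * om * c_
  phidd <- wdd * A * s_ + 2 * wd * A * om * c_ - w * A * om^2 * s_
  list(phi = phi, phid = phid, phidd = phidd)
}

#' Simulate a wrist-IMU drumming stream with analytic ground truth
#'
#' Generates the device-frame sensor signals of the single-axis swing
#' model.  With the device z-axis along the forearm (wrist to elbow) and
#' the swing about the device y-axis, the noise-free specific force is
#' \deqn{a = (g\cos\phi - r\ddot\phi,\; 0,\; g\sin\phi + r\dot\phi^2)}
#' (gravity reaction plus tangential and centripetal terms at radius
#' r = 0.223 m) and the gyro reads \eqn{(0, \dot\phi, 0)}.  Gaussian noise
#' is added per axis.
#'
#' The returned `truth` evaluates the defining formulas of both biomarkers
#' on the analytic trajectory: average elevation as the mean of per-window
#' (1 s) maxima of \eqn{\phi} on a dense 1 kHz grid, and average velocity
#' as the mean of \eqn{|\dot\phi| r} on the same grid restricted to
#' non-rest time.  A 1 kHz sample counts as rest when its analytic motion
#' acceleration magnitude \eqn{r\sqrt{\ddot\phi^2 + \dot\phi^4}} is at or
#' below `rest_threshold_ms2`; per-sample rest labels on the stream grid
#' use the same rule.
#'
#' @param params a [motion_params()].
#' @param radius_m rotation radius (m), default 0.223.
#' @param gravity_ms2 gravity, default 9.80665.
#' @param rest_threshold_ms2 threshold defining true rest labels, 0.1.
#' @return list with `stream` (a regularized [imu_stream()]) and `truth`
#'   (list: `avg_elevation_deg`, `avg_velocity_ms`, `phi_deg` on the
#'   stream grid, `rest` labels, `params`).
#' @export
simulate_drumming_motion <- function(params, radius_m = 0.223,
                                     gravity_ms2 = 9.80665,
                                     rest_threshold_ms2 = 0.1) {
  stopifnot(inherits(params, "synthetic_motion_params"))
  g <- gravity_ms2; r <- radius_m
  t <- seq(0, params$duration_s, by = 1 / params$rate_hz)
  tr <- motion_trajectory(params, t)
  n <- length(t)
  noise <- withr::with_seed(params$seed, {
    list(a = matrix(stats::rnorm(3 * n, 0, params$accel_noise_sd_ms2), n),
         g = matrix(stats::rnorm(3 * n, 0, params$gyro_noise_sd_rads), n))
  })
  accel <- cbind(g * cos(tr$phi) - r * tr$phidd, 0,
                 g * sin(tr$phi) + r * tr$phid^2) + noise$a
  gyro <- cbind(0, tr$phid, 0) + noise$g
  stream <- imu_stream(
    data.frame(t = t, ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
               gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3]),
    nominal_rate = params$rate_hz,
    subject_id = sprintf("sim-seed%d", params$seed),
    regularized = TRUE)

  td <- seq(0, params$duration_s, by = 1e-3)
  trd <- motion_trajectory(params, td)
  motion_mag <- r * sqrt(trd$phidd^2 + trd$phid^4)
  rest_d <- motion_mag <= rest_threshold_ms2
  wlen <- 1000L
  n_win <- length(td) %/% wlen
  idx <- rep(seq_len(n_win), each = wlen)
  wmax <- tapply(trd$phi[seq_len(n_win * wlen)] * 180 / pi, idx, max)
  vel_truth <- if (any(!rest_d)) mean(abs(trd$phid[!rest_d])) * r else 0
  motion_mag_s <- r * sqrt(tr$phidd^2 + tr$phid^4)
  truth <- list(avg_elevation_deg = mean(wmax),
                avg_velocity_ms = vel_truth,
                phi_deg = tr$phi * 180 / pi,
                rest = motion_mag_s <= rest_threshold_ms2,
                params = params)
  list(stream = stream, truth = truth)
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the pilot cohort's published structure: n = 16 with
#' a 12:4 woman:man split, marginal means and SDs from the published
#' summary table ([pilot_cohort_summary()]), one missing handgrip value,
#' and a target Spearman correlation matrix whose entries are the
#' published pairwise estimates for the 11 jointly tabulated measures
#' (variables outside that set are generated independently).
#'
#' @param n cohort size.
#' @param means,sds named numeric vectors of marginal means/SDs; defaults
#'   from the published table.
#' @param target_rho target Spearman correlation matrix (named dimnames);
#'   default [pilot_target_rho()].
#' @param sex_ratio named vector `c(women = , men = )` summing to `n`.
#' @param missing_grip_count number of grip values set missing (default 1).
#' @param seed integer seed.
#' @return an object of class `synthetic_cohort_params`.
#' @export
cohort_params <- function(n = 16, means = NULL, sds = NULL,
                          target_rho = NULL,
                          sex_ratio = c(women = 12, men = 4),
                          missing_grip_count = 1, seed = 1) {
  ref <- pilot_cohort_summary()
  if (is.null(means)) means <- stats::setNames(ref$mean_all, ref$variable)
  if (is.null(sds)) sds <- stats::setNames(ref$sd_all, ref$variable)
  if (is.null(target_rho)) target_rho <- pilot_target_rho()
  if (!isTRUE(all.equal(unname(sum(sex_ratio)), n)))
    stop("sex_ratio must sum to n")
  if (missing_grip_count < 0 || missing_grip_count > n)
    stop("missing_grip_count must lie in [0, n]")
  if (!isSymmetric(target_rho) || any(abs(diag(target_rho) - 1) > 1e-12))
    stop("target_rho must be symmetric with unit diagonal")
  structure(list(n = n, means = means, sds = sds, target_rho = target_rho,
                 sex_ratio = sex_ratio,
                 missing_grip_count = missing_grip_count, seed = seed),
            class = "synthetic_cohort_params")
}

#' Published pairwise Spearman targets of the pilot cohort
#'
#' The 11 x 11 Spearman correlation matrix of the jointly tabulated pilot
#' measures, used as the generator's default target.
#'
#' @return symmetric unit-diagonal matrix with variable dimnames.
#' @export
pilot_target_rho <- function() {
  v <- c("age", "length_of_stay", "mmse", "avg_velocity_ms",
         "avg_elevation_deg", "grip_kg", "active_flexion_deg",
         "passive_flexion_deg", "bmi", "smi", "arm_muscle_kg")
  m <- diag(11)
  dimnames(m) <- list(v, v)
  set <- function(a, b, r) {
    m[a, b] <<- r; m[b, a] <<- r
  }
  set("length_of_stay", "age", 0.1600)
  set("mmse", "age", 0.2092); set("mmse", "length_of_stay", -0.2087)
  set("avg_velocity_ms", "age", -0.0637)
  set("avg_velocity_ms", "length_of_stay", -0.2399)
  set("avg_velocity_ms", "mmse", -0.0354)
  set("avg_elevation_deg", "age", 0.4264)
  set("avg_elevation_deg", "length_of_stay", -0.4341)
  set("avg_elevation_deg", "mmse", 0.5925)
  set("avg_elevation_deg", "avg_velocity_ms", 0.1353)
  set("grip_kg", "age", -0.2942); set("grip_kg", "length_of_stay", -0.4254)
  set("grip_kg", "mmse", 0.5473); set("grip_kg", "avg_velocity_ms", 0.0339)
  set("grip_kg", "avg_elevation_deg", 0.3528)
  set("active_flexion_deg", "age", -0.2236)
  set("active_flexion_deg", "length_of_stay", -0.3427)
  set("active_flexion_deg", "mmse", 0.3891)
  set("active_flexion_deg", "avg_velocity_ms", 0.5668)
  set("active_flexion_deg", "avg_elevation_deg", 0.2052)
  set("active_flexion_deg", "grip_kg", 0.5459)
  set("passive_flexion_deg", "age", 0.0772)
  set("passive_flexion_deg", "length_of_stay", -0.0790)
  set("passive_flexion_deg", "mmse", 0.3903)
  set("passive_flexion_deg", "avg_velocity_ms", 0.2130)
  set("passive_flexion_deg", "avg_elevation_deg", 0.2294)
  set("passive_flexion_deg", "grip_kg", 0.4425)
  set("passive_flexion_deg", "active_flexion_deg", 0.6248)
  set("bmi", "age", 0.0178); set("bmi", "length_of_stay", 0.1104)
  set("bmi", "mmse", 0.1268); set("bmi", "avg_velocity_ms", 0.1147)
  set("bmi", "avg_elevation_deg", 0.2118); set("bmi", "grip_kg", 0.3114)
  set("bmi", "active_flexion_deg", 0.1904)
  set("bmi", "passive_flexion_deg", 0.2577)
  set("smi", "age", -0.2517); set("smi", "length_of_stay", 0.0015)
  set("smi", "mmse", 0.1857); set("smi", "avg_velocity_ms", 0.0294)
  set("smi", "avg_elevation_deg", 0.1206); set("smi", "grip_kg", 0.2583)
  set("smi", "active_flexion_deg", -0.0472)
  set("smi", "passive_flexion_deg", -0.3277); set("smi", "bmi", 0.3971)
  set("arm_muscle_kg", "age", -0.2550)
  set("arm_muscle_kg", "length_of_stay", -0.0553)
  set("arm_muscle_kg", "mmse", 0.3734)
  set("arm_muscle_kg", "avg_velocity_ms", -0.1767)
  set("arm_muscle_kg", "avg_elevation_deg", 0.1267)
  set("arm_muscle_kg", "grip_kg", 0.6061)
  set("arm_muscle_kg", "active_flexion_deg", 0.1397)
  set("arm_muscle_kg", "passive_flexion_deg", -0.0522)
  set("arm_muscle_kg", "bmi", 0.6274)
  set("arm_muscle_kg", "smi", 0.7629)
  m
}

#' Simulate a cohort with a target Spearman correlation structure
#'
#' Gaussian copula: the target Spearman matrix is converted to Pearson
#' parameters via \eqn{r = 2\sin(\pi\rho_s/6)}, repaired to the nearest
#' positive-semidefinite correlation matrix if needed, and multivariate
#' normal scores are transformed to Gaussian marginals with the requested
#' means and SDs (which preserves rank correlations).  Variables with a
#' marginal but no row in the target matrix are generated independently.
#' MMSE is rounded and clipped to \eqn{[0, 30]}; the daily-living ordinal
#' scale is rounded and clipped to ranks 1-7; masses, days, velocities and
#' grip are clipped at 0.  Sex is assigned by a seeded permutation of the
#' requested 12:4 split (independently of the other variables, which are
#' not tabulated jointly with sex), and `missing_grip_count` grip values
#' are set missing.
#'
#' @param params a [cohort_params()].
#' @return data.frame with columns `id`, `sex` and the marginal variables;
#'   byte-identical for identical seeds.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "synthetic_cohort_params"))
  vars <- names(params$means)
  rho_vars <- intersect(rownames(params$target_rho), vars)
  extra <- setdiff(vars, rho_vars)
  k <- length(rho_vars)
  pearson <- 2 * sin(pi * params$target_rho[rho_vars, rho_vars] / 6)
  diag(pearson) <- 1
  ev <- eigen(pearson, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    pearson <- as.matrix(Matrix::nearPD(pearson, corr = TRUE)$mat)
    ev <- eigen(pearson, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("target correlation matrix is not positive semidefinite after repair")
  }
  L <- chol(pearson)
  withr::with_seed(params$seed, {
    Z <- matrix(stats::rnorm(params$n * k), params$n) %*% L
    colnames(Z) <- rho_vars
    Zx <- matrix(stats::rnorm(params$n * length(extra)), params$n)
    colnames(Zx) <- extra
    Zall <- cbind(Z, Zx)[, vars, drop = FALSE]
    out <- as.data.frame(sweep(sweep(Zall, 2, params$sds[vars], "*"),
                               2, params$means[vars], "+"))
    sex <- sample(rep(c("woman", "man"), params$sex_ratio))
    grip_missing <- if (params$missing_grip_count > 0)
      sample.int(params$n, params$missing_grip_count) else integer(0)
    if ("mmse" %in% vars) out$mmse <- pmin(30, pmax(0, round(out$mmse)))
    if ("id_adl" %in% vars) out$id_adl <- pmin(7, pmax(1, round(out$id_adl)))
    for (v in intersect(c("length_of_stay", "height_cm", "weight_kg", "bmi",
                          "smi", "arm_muscle_kg", "grip_kg",
                          "avg_velocity_ms", "active_flexion_deg",
                          "passive_flexion_deg"), vars))
      out[[v]] <- pmax(0, out[[v]])
    for (v in intersect(c("active_flexion_deg", "passive_flexion_deg"), vars))
      out[[v]] <- pmin(180, out[[v]])
    if ("grip_kg" %in% vars && length(grip_missing) > 0)
      out$grip_kg[grip_missing] <- NA_real_
    cbind(data.frame(id = sprintf("S%02d", seq_len(params$n)), sex = sex,
                     stringsAsFactors = FALSE),
          out)
  })
}
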