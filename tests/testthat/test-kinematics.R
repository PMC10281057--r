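test_that("gravity estimation recovers static and tilted orientations", {
  o <- estimate_gravity(static_stream(c(0, 0, 9.81)))
  expect_equal(unname(tail(as.matrix(o[, c("vx", "vy", "vz")]), 1)[1, ]),
               c(0, 0, 1), tolerance = 1e-9)

  tilt <- static_stream(9.81 * c(0, sin(pi / 6), cos(pi / 6)))
  o2 <- estimate_gravity(tilt)
  expect_equal(o2$vz[nrow(o2)], cos(pi / 6), tolerance = 1e-9)

  # near-free-fall accelerometer magnitudes carry no gravity reference
  ff <- static_stream(c(0, 0, 0.01))
  expect_error(estimate_gravity(ff, kinematic_config(orientation_method = "accel")),
               "degenerate")
})

test_that("gravity tracking of a noisy swing stays within 3 degrees", {
  sim <- simulate_drumming_motion(
    motion_params(accel_noise_sd_ms2 = 0.2, gyro_noise_sd_rads = 0.02,
                  seed = 21))
  o <- estimate_gravity(sim$stream)
  phi <- sim$truth$phi_deg * pi / 180
  up <- cbind(cos(phi), 0, sin(phi))
  dots <- rowSums(as.matrix(o[, c("vx", "vy", "vz")]) * up)
  ang_err <- acos(pmax(-1, pmin(1, dots))) * 180 / pi
  expect_lt(mean(ang_err), 3)
})

test_that("rest filter separates rest from exercise", {
  # a perfectly static stream is all rest
  rf <- rest_filter(static_stream())
  expect_equal(rf$n_removed, n_samples(static_stream()))
  expect_null(rf$stream)

  # constant 0.5 m/s^2 linear acceleration (alternating sign so the
  # low-pass cannot absorb it into the gravity estimate): nothing removed
  t <- seq(0, 10, by = 0.05)
  s <- imu_stream(data.frame(t = t, ax = 0.5 * (-1)^(seq_along(t)),
                             ay = 0, az = 9.80665, gx = 0, gy = 0, gz = 0),
                  regularized = TRUE)
  rf2 <- rest_filter(s)
  expect_lte(rf2$n_removed, 5)  # a few samples while the estimate settles
  expect_gt(sum(rf2$keep), 0.95 * n_samples(s))

  # an inserted rest segment is removed, up to filter settling
  sim <- simulate_drumming_motion(
    motion_params(rest_segments = list(c(20, 23)), seed = 31))
  rf3 <- rest_filter(sim$stream)
  true_rest <- sum(sim$truth$rest)
  settle <- 2 * 20  # two gravity time constants of samples
  expect_lte(abs(rf3$n_removed - true_rest), settle)
})

test_that("velocity metric matches its definitional oracles", {
  # constant-rate rotation: acos increment recovers omega exactly
  vel <- average_arm_velocity(rotation_stream(omega = 1))
  expect_equal(vel, 0.223, tolerance = 0.01)

  # identical successive orientations give zero velocity: a constant
  # off-vertical specific force fixes the orientation estimate while its
  # residual stays above a lowered rest threshold
  t <- seq(0, 10, by = 0.05)
  s <- imu_stream(data.frame(t = t, ax = 0.5, ay = 0, az = 9.80665,
                             gx = 0, gy = 0, gz = 0),
                  regularized = TRUE)
  expect_lt(average_arm_velocity(s, kinematic_config(rest_threshold_ms2 = 0.005)),
            1e-6)

  # simulated swing vs the dense analytic oracle
  sim <- simulate_drumming_motion(
    motion_params(accel_noise_sd_ms2 = 0, gyro_noise_sd_rads = 0))
  vel2 <- average_arm_velocity(sim$stream)
  expect_lt(abs(vel2 / sim$truth$avg_velocity_ms - 1), 0.02)

  expect_error(average_arm_velocity(static_stream()), "insufficient data")
})

test_that("velocity is invariant to a fixed rotation of the device frame", {
  # the lever-arm compensation is anchored to the forearm-z convention, so
  # rotation invariance is a property of the uncompensated estimator
  cfg <- kinematic_config(lever_arm_comp = FALSE)
  sim <- simulate_drumming_motion(motion_params(duration_s = 20, seed = 41))
  axis <- c(1, 2, 3) / sqrt(14); ang <- 0.7
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  v1 <- average_arm_velocity(sim$stream, cfg)
  v2 <- average_arm_velocity(rotate_stream(sim$stream, R), cfg)
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("velocity is linear in the rotation radius for a fixed orientation", {
  sim <- simulate_drumming_motion(motion_params(duration_s = 20, seed = 43))
  cfg1 <- kinematic_config(radius_m = 0.223)
  cfg2 <- kinematic_config(radius_m = 0.446)
  o <- estimate_gravity(sim$stream, cfg1)
  v1 <- average_arm_velocity(sim$stream, cfg1, o)
  v2 <- average_arm_velocity(sim$stream, cfg2, o)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
})

test_that("elevation metric matches static tilts and the swing oracle", {
  # device z-axis horizontal: zero elevation
  s <- static_stream(c(9.80665, 0, 0))
  expect_equal(average_elevation_angle(s), 0, tolerance = 1e-9)

  # gravity component 0.5 along z: 30 degrees
  s2 <- static_stream(9.80665 * c(sqrt(1 - 0.25), 0, 0.5))
  expect_equal(average_elevation_angle(s2), 30, tolerance = 1e-6)

  # analytic tilt recovered within 0.5 degrees, noise-free
  s3 <- static_stream(9.80665 * c(cos(0.3), 0, sin(0.3)))
  expect_lt(abs(average_elevation_angle(s3) - 0.3 * 180 / pi), 0.5)

  # swing: mean of per-second maxima of 15 + 10 sin(2 pi 1.5 t) is ~25
  sim <- simulate_drumming_motion(
    motion_params(accel_noise_sd_ms2 = 0, gyro_noise_sd_rads = 0))
  est <- average_elevation_angle(sim$stream)
  expect_lt(abs(est - sim$truth$avg_elevation_deg), 0.5)
  expect_equal(sim$truth$avg_elevation_deg, 25, tolerance = 1e-3)

  expect_error(average_elevation_angle(static_stream(duration = 0.4)),
               "no complete")
})

test_that("elevation responds monotonically to a constant offset", {
  est <- vapply(c(0, 5, 10, 20), function(off) {
    sim <- simulate_drumming_motion(
      motion_params(elevation_offset_deg = off, duration_s = 20, seed = 51))
    average_elevation_angle(sim$stream)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("summarize_kinematics bundles both metrics with QC counts", {
  sim <- simulate_drumming_motion(motion_params(seed = 61))
  ks <- summarize_kinematics(sim$stream)
  expect_equal(ks$n_windows, 60)
  expect_equal(ks$n_samples_total, 1201)
  expect_true(is.finite(ks$avg_velocity_ms) && ks$avg_velocity_ms >= 0)
  expect_true(abs(ks$avg_elevation_deg) <= 90)

  # an all-rest stream yields a missing velocity but a valid elevation
  ks2 <- summarize_kinematics(static_stream(9.80665 * c(cos(0.3), 0, sin(0.3))))
  expect_true(is.na(ks2$avg_velocity_ms))
  expect_equal(ks2$avg_elevation_deg, 0.3 * 180 / pi, tolerance = 0.5)
  expect_equal(ks2$n_samples_rest_removed, ks2$n_samples_total)
})

test_that("kinematic_config rejects non-positive fields", {
  expect_error(kinematic_config(radius_m = 0), "positive")
  expect_error(kinematic_config(window_s = -1), "positive")
})
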