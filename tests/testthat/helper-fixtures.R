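# Shared fixtures built in code at test time.

# A well-formed IMU CSV with given rows (gyro columns in deg/s on disk).
write_imu_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("t_s,ax,ay,az,gx,gy,gz", rows), path)
  path
}

# Uniform static stream: constant accel direction, zero gyro.
static_stream <- function(accel = c(0, 0, 9.80665), duration = 10, rate = 20) {
  t <- seq(0, duration, by = 1 / rate)
  imu_stream(data.frame(t = t,
                        ax = accel[1], ay = accel[2], az = accel[3],
                        gx = 0, gy = 0, gz = 0),
             nominal_rate = rate, regularized = TRUE)
}

# Constant-rate planar rotation: gravity direction sweeps the x-z plane at
# omega rad/s; gyro reads +omega about the device y-axis.
rotation_stream <- function(omega = 1, duration = 60, rate = 20,
                            g = 9.80665) {
  t <- seq(0, duration, by = 1 / rate)
  phi <- omega * t
  imu_stream(data.frame(t = t, ax = g * cos(phi), ay = 0, az = g * sin(phi),
                        gx = 0, gy = omega, gz = 0),
             nominal_rate = rate, regularized = TRUE)
}

# Independent brute-force permutation oracle for the Spearman test:
# enumerates permutations itself and uses stats::cor directly.
brute_perm_spearman <- function(x, y, alternative) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  rho_obs <- stats::cor(x, y, method = "spearman")
  rhos <- vapply(perms(seq_along(y)),
                 function(p) stats::cor(x, y[p], method = "spearman"),
                 numeric(1))
  tol <- 1e-10
  switch(alternative,
         greater = mean(rhos >= rho_obs - tol),
         less = mean(rhos <= rho_obs + tol),
         two_sided = mean(abs(rhos) >= abs(rho_obs) - tol))
}

# Rotate every sample of a stream by a fixed rotation matrix.
rotate_stream <- function(stream, R) {
  d <- stream$data
  a <- as.matrix(d[, c("ax", "ay", "az")]) %*% t(R)
  g <- as.matrix(d[, c("gx", "gy", "gz")]) %*% t(R)
  d[, c("ax", "ay", "az")] <- a
  d[, c("gx", "gy", "gz")] <- g
  out <- stream
  out$data <- d
  out
}
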