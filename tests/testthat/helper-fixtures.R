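# Shared fixture builders: everything is generated in code at test time.

REF_FIELD <- c(20, 0, sqrt(40^2 - 20^2))

# trace with constant sensor readings (defaults: static, identity orientation)
const_trace <- function(duration, gyro = c(0, 0, 0), accel = c(0, 0, -1),
                        mag = REF_FIELD, rate = 128) {
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1L) / rate
  mimu_trace(tt,
             matrix(gyro, n, 3, byrow = TRUE),
             matrix(accel, n, 3, byrow = TRUE),
             matrix(mag, n, 3, byrow = TRUE), rate)
}

# identity orientation series on the same grid as a trace or time vector
identity_series <- function(x) {
  tt <- if (inherits(x, "mimu_trace")) x$time else x
  orientation_series(tt, matrix(rep(c(0, 0, 0, 1), each = length(tt)),
                                ncol = 4))
}

# static ground truth at identity with optional GGF field disturbance rows
static_truth <- function(duration, rate = 128, disturbance = NULL) {
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1L) / rate
  if (is.null(disturbance)) disturbance <- matrix(0, n, 3)
  ground_truth(identity_series(tt), matrix(0, n, 3), matrix(0, n, 3),
               disturbance, rep(TRUE, n), rate)
}

# manual routine with a compressed schedule, for cheap tests
short_manual <- function(seed, duration = 30) {
  make_manual_routine(seed = seed, duration = duration,
                      segment_time = 2, pause_time = 1)
}

noiseless_model <- function(...) {
  sensor_model(gyro_noise_sd = 0, accel_noise_sd = 0, mag_noise_sd = 0, ...)
}

# angle (deg) between two unit quaternions, double-cover safe
quat_angle_deg <- function(a, b) {
  quat_angle(quat_multiply(a, quat_conjugate(b))) * 180 / pi
}

# wrap an angle difference (deg) into [-180, 180]
wrap180 <- function(x) x - 360 * round(x / 360)
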