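#' Complementary-filter gain from the gyroscope error level
#'
#' The single tuning parameter of the gradient-descent complementary filter
#' is the gain `beta = sqrt(3/4) * omega_max`, where `omega_max` is the
#' maximum gyroscope measurement error, conventionally taken as three times
#' the gyro white-noise standard deviation. Input and output share the same
#' angular-rate unit.
#'
#' @param omega_max_error maximum gyroscope error (e.g. deg/s), >= 0.
#' @return The gain `sqrt(3/4) * omega_max_error`, in the input unit.
#' @export
beta_from_gyro_error <- function(omega_max_error) {
  if (!is.numeric(omega_max_error) || omega_max_error < 0)
    stop("'omega_max_error' must be >= 0")
  sqrt(3 / 4) * omega_max_error
}

#' @rdname beta_from_gyro_error
#' @param noise_sd gyroscope white-noise standard deviation; the maximum
#'   error is taken as three times this value.
#' @export
beta_from_noise_sd <- function(noise_sd) beta_from_gyro_error(3 * noise_sd)

#' Complementary-filter parameters
#'
#' @param beta filter gain in rad/s (default 0.1 rad/s, i.e. 5.73 deg/s).
#' @return Object of class `cf_params`.
#' @export
cf_params <- function(beta = 0.1) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("'beta' must be a non-negative scalar (rad/s)")
  structure(list(beta = beta), class = "cf_params")
}

#' One step of the gradient-descent complementary filter
#'
#' The gyro-driven quaternion propagation (the same exact constant-rate step
#' as the numerical-integration estimator) is corrected by a single
#' normalized gradient-descent iteration on the stacked
#' accelerometer/magnetometer objective: the rotated gravity direction must
#' match the normalized specific force, and the rotated reference field must
#' match the normalized magnetic measurement. The magnetic reference is
#' recomputed at every step from the measurement itself, rotated into the
#' global frame by the current estimate and flattened to have a null Y
#' component — so the magnetometer constrains the heading while leaving the
#' attitude untouched by ferromagnetic dip changes. A zero-magnitude
#' accelerometer or magnetometer sample drops the corresponding objective
#' block for that step.
#'
#' @param q current unit quaternion (ULF-to-GGF).
#' @param gyro gyro sample, deg/s.
#' @param accel accelerometer sample, g.
#' @param mag magnetometer sample, uT.
#' @param dt time step, s.
#' @param params a [cf_params()].
#' @return Updated unit quaternion.
#' @export
cf_step <- function(q, gyro, accel, mag, dt, params = cf_params()) {
  if (dt <= 0) stop("'dt' must be positive")
  q_pred <- integrate_step(q, gyro * pi / 180, dt)
  if (params$beta == 0) return(q_pred)

  an <- sqrt(sum(accel^2))
  mn <- sqrt(sum(mag^2))
  f <- NULL; J <- NULL
  if (an > 1e-9) {
    a_hat <- accel / an
    f <- quat_rotate(quat_conjugate(q_pred), c(0, 0, -1)) - a_hat
    J <- d_rt_v_dq(q_pred, c(0, 0, -1))
  }
  if (mn > 1e-9) {
    m_hat <- mag / mn
    h <- quat_rotate(q_pred, m_hat)
    b_ref <- c(sqrt(h[1L]^2 + h[2L]^2), 0, h[3L])
    f <- c(f, quat_rotate(quat_conjugate(q_pred), b_ref) - m_hat)
    J <- rbind(J, d_rt_v_dq(q_pred, b_ref))
  }
  if (is.null(f)) return(q_pred)

  grad <- as.numeric(crossprod(J, f))
  gn <- sqrt(sum(grad^2))
  if (gn < 1e-12) return(q_pred)
  quat_normalize(q_pred - params$beta * dt * grad / gn)
}

#' Run the complementary filter over a trace
#'
#' Initializes from the null quaternion (global frame defined by the initial
#' static posture) and applies [cf_step()] over the whole trace. The filter
#' is stateless beyond the quaternion: no noise statistics or gating are
#' used.
#'
#' @param trace a [mimu_trace()] (bias-corrected gyro recommended).
#' @param params a [cf_params()].
#' @param q0 initial quaternion (default identity).
#' @return An [orientation_series()] in the ULF-to-GGF convention.
#' @export
cf_estimator <- function(trace, params = cf_params(), q0 = quat_identity()) {
  stopifnot(inherits(trace, "mimu_trace"), inherits(params, "cf_params"))
  n <- length(trace$time)
  if (n < 2L) stop("trace too short")
  Q <- matrix(0, n, 4L)
  q <- quat_normalize(q0)
  Q[1L, ] <- q
  for (k in seq_len(n - 1L)) {
    q <- cf_step(q, trace$gyro[k, ], trace$accel[k + 1L, ],
                 trace$mag[k + 1L, ], trace$time[k + 1L] - trace$time[k],
                 params)
    Q[k + 1L, ] <- q
  }
  orientation_series(trace$time, Q)
}
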