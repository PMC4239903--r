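#' Parameters of the stochastic (extended Kalman) filter
#'
#' Eight tuning parameters of the quaternion EKF, in the units in which they
#' are customarily reported: process noise statistics (gyro white noise,
#' gyro bias random walk, magnetic variation intensity and correlation
#' time), measurement noise statistics (accelerometer in milli-g, i.e.
#' g/10^3, and magnetometer in uT) and the vector-selection thresholds
#' (acceleration in milli-g, magnetic magnitude in uT), plus the
#' direction-consistency (dip-angle) gate. Two named presets are provided
#' for the manual-routine and locomotion scenarios.
#'
#' @param preset `"manual"` or `"locomotion"`; individual arguments
#'   override the preset values.
#' @param gyro_sd gyro process noise SD, deg/s.
#' @param gyro_bias_walk_sd gyro bias random-walk SD, deg/s^2.
#' @param mag_walk_sd magnetic-variation process noise intensity, uT/s.
#' @param mag_tau magnetic-variation correlation time, s.
#' @param accel_meas_sd accelerometer measurement noise SD, g/10^3.
#' @param mag_meas_sd magnetometer measurement noise SD, uT.
#' @param accel_gate acceleration-magnitude gate, g/10^3.
#' @param mag_gate magnetic-magnitude gate, uT.
#' @param dip_gate_deg direction gate on the dip-angle deviation, degrees.
#' @return Object of class `sf_params`.
#' @export
sf_params <- function(preset = c("manual", "locomotion"),
                      gyro_sd = NULL, gyro_bias_walk_sd = NULL,
                      mag_walk_sd = NULL, mag_tau = NULL,
                      accel_meas_sd = NULL, mag_meas_sd = NULL,
                      accel_gate = NULL, mag_gate = NULL,
                      dip_gate_deg = NULL) {
  preset <- match.arg(preset)
  p <- switch(preset,
    manual = list(gyro_sd = 2.5, gyro_bias_walk_sd = 0, mag_walk_sd = 1,
                  mag_tau = 1, accel_meas_sd = 10, mag_meas_sd = 3,
                  accel_gate = 40, mag_gate = 5, dip_gate_deg = 15),
    locomotion = list(gyro_sd = 2.5, gyro_bias_walk_sd = 0.01,
                      mag_walk_sd = 10, mag_tau = 1, accel_meas_sd = 2.5,
                      mag_meas_sd = 3, accel_gate = 10, mag_gate = 5,
                      dip_gate_deg = 15))
  for (nm in names(p)) {
    ov <- get(nm)
    if (!is.null(ov)) p[[nm]] <- ov
  }
  if (any(unlist(p) < 0)) stop("sf parameters must be >= 0")
  p$preset <- preset
  structure(p, class = "sf_params")
}

#' EKF state
#'
#' The ten-state vector of the stochastic filter — orientation quaternion,
#' gyro bias (deg/s) and global-frame magnetic disturbance (uT) — with its
#' 10 x 10 covariance. The default initial covariance is diag(1e-4) on the
#' quaternion components, (0.5 deg/s)^2 on the bias and (5 uT)^2 on the
#' disturbance.
#'
#' @param q unit quaternion (ULF-to-GGF), scalar last.
#' @param gyro_bias 3-vector, deg/s.
#' @param mag_disturbance 3-vector in GGF, uT.
#' @param covariance 10 x 10 symmetric positive semi-definite matrix.
#' @return Object of class `sf_state`.
#' @export
sf_state <- function(q = quat_identity(), gyro_bias = c(0, 0, 0),
                     mag_disturbance = c(0, 0, 0),
                     covariance = diag(c(rep(1e-4, 4), rep(0.5^2, 3),
                                         rep(5^2, 3)))) {
  stopifnot(length(gyro_bias) == 3L, length(mag_disturbance) == 3L,
            all(dim(covariance) == c(10L, 10L)))
  structure(list(q = quat_normalize(q), gyro_bias = gyro_bias,
                 mag_disturbance = mag_disturbance, covariance = covariance),
            class = "sf_state")
}

repair_psd <- function(P) {
  P <- (P + t(P)) / 2
  e <- eigen(P, symmetric = TRUE)
  if (min(e$values) < -1e-9) {
    warning("non-PSD covariance repaired by eigenvalue clipping")
    vals <- pmax(e$values, 0)
    P <- e$vectors %*% (vals * t(e$vectors))
  }
  P
}

#' EKF prediction step
#'
#' Propagates the quaternion with the bias-corrected gyro sample through the
#' exact constant-rate step, applies the first-order Gauss-Markov decay
#' `exp(-dt/tau)` to the magnetic-disturbance state, and propagates the
#' covariance with the linearized transition. Process noise: the quaternion
#' block inherits the gyro white noise through the kinematic map, the bias
#' block grows by `(gyro_bias_walk_sd * dt)^2` and the magnetic block by
#' `(mag_walk_sd * dt)^2` per axis.
#'
#' @param state an [sf_state()].
#' @param gyro gyro sample 3-vector, deg/s.
#' @param dt time step, s.
#' @param params an [sf_params()].
#' @return Updated [sf_state()].
#' @export
sf_predict <- function(state, gyro, dt, params) {
  if (dt <= 0) stop("'dt' must be positive")
  P <- state$covariance
  if (any(diag(P) < 0) || any(!is.finite(P))) P <- repair_psd(P)
  q <- state$q
  omega_dps <- gyro - state$gyro_bias
  omega_rad <- omega_dps * (pi / 180)

  nrm <- sqrt(sum(omega_rad^2))
  dq <- if (nrm * dt < 1e-14) quat_identity()
  else c(omega_rad / nrm * sin(nrm * dt / 2), cos(nrm * dt / 2))
  q_new <- quat_multiply(q, dq)

  Xi <- xi_mat(q)
  Fm <- diag(10)
  Fm[1:4, 1:4] <- mat_right(dq)
  Fm[1:4, 5:7] <- -(dt / 2) * (pi / 180) * Xi
  phi <- exp(-dt / params$mag_tau)
  Fm[8:10, 8:10] <- phi * diag(3)

  Qn <- matrix(0, 10, 10)
  sg <- params$gyro_sd * pi / 180
  Qn[1:4, 1:4] <- (dt / 2)^2 * sg^2 * tcrossprod(Xi)
  Qn[5:7, 5:7] <- (params$gyro_bias_walk_sd * dt)^2 * diag(3)
  Qn[8:10, 8:10] <- (params$mag_walk_sd * dt)^2 * diag(3)

  P_new <- Fm %*% P %*% t(Fm) + Qn
  sf_state(q_new, state$gyro_bias, phi * state$mag_disturbance,
           (P_new + t(P_new)) / 2)
}

ekf_correct <- function(state, y, H, Rm) {
  P <- state$covariance
  S <- H %*% P %*% t(H) + Rm
  K <- P %*% t(H) %*% solve(S)
  dx <- as.numeric(K %*% y)
  IKH <- diag(10) - K %*% H
  P_new <- IKH %*% P %*% t(IKH) + K %*% Rm %*% t(K)
  sf_state(quat_normalize(state$q + dx[1:4]),
           state$gyro_bias + dx[5:7],
           state$mag_disturbance + dx[8:10],
           (P_new + t(P_new)) / 2)
}

#' EKF measurement update with vector selection
#'
#' Sequentially applies the accelerometer and the magnetometer updates, each
#' guarded by its gate. The accelerometer update runs only when the measured
#' specific-force magnitude is within `accel_gate` milli-g of 1 g (the unit
#' is quasi-static, so the measurement is the rotated gravity direction).
#' The magnetometer update runs only when the measured field magnitude is
#' within `mag_gate` uT of the reference magnitude AND the dip angle of the
#' measured field, rotated into the global frame by the current estimate,
#' deviates from the reference dip by less than the direction gate. The
#' magnetometer model includes the magnetic-disturbance state, rotated into
#' the sensor frame, which is how slow field variations are absorbed without
#' bending the heading. A gated-out sample leaves the state exactly equal to
#' the prediction.
#'
#' @param state an [sf_state()] (after prediction).
#' @param accel accelerometer sample 3-vector, g.
#' @param mag magnetometer sample 3-vector, uT.
#' @param params an [sf_params()].
#' @param reference_field local reference field 3-vector in GGF, uT.
#' @return Updated [sf_state()], with attribute `accepted` (logical 2-vector:
#'   accel, mag).
#' @export
sf_update <- function(state, accel, mag, params, reference_field) {
  acc_ok <- abs(sqrt(sum(accel^2)) - 1) <= params$accel_gate / 1000
  if (acc_ok) {
    q <- state$q
    h <- quat_rotate(quat_conjugate(q), c(0, 0, -1))
    H <- cbind(d_rt_v_dq(q, c(0, 0, -1)), matrix(0, 3, 6))
    state <- ekf_correct(state, accel - h, H,
                         (params$accel_meas_sd / 1000)^2 * diag(3))
  }

  ref_mag <- sqrt(sum(reference_field^2))
  mag_norm <- sqrt(sum(mag^2))
  mag_ok <- abs(mag_norm - ref_mag) <= params$mag_gate
  if (mag_ok && mag_norm > 0) {
    m_g <- quat_rotate(state$q, mag)
    dip_meas <- atan2(m_g[3L], sqrt(m_g[1L]^2 + m_g[2L]^2))
    dip_ref <- atan2(reference_field[3L],
                     sqrt(reference_field[1L]^2 + reference_field[2L]^2))
    mag_ok <- abs(dip_meas - dip_ref) <= params$dip_gate_deg * pi / 180
  }
  if (mag_ok) {
    q <- state$q
    v <- reference_field + state$mag_disturbance
    h <- quat_rotate(quat_conjugate(q), v)
    H <- cbind(d_rt_v_dq(q, v), matrix(0, 3, 3), t(quat_to_matrix(q)))
    state <- ekf_correct(state, mag - h, H, params$mag_meas_sd^2 * diag(3))
  }
  attr(state, "accepted") <- c(accel = acc_ok, mag = mag_ok)
  state
}

triad_init <- function(accel, mag, reference_field) {
  # orthonormal frame from the gravity and field directions, matched between
  # body measurements and their global references
  frame_of <- function(down, field) {
    d <- down / sqrt(sum(down^2))
    e <- field - sum(field * d) * d
    e <- e / sqrt(sum(e^2))
    cbind(e, c(d[2] * e[3] - d[3] * e[2], d[3] * e[1] - d[1] * e[3],
               d[1] * e[2] - d[2] * e[1]), d)
  }
  Rb <- frame_of(-accel, mag)
  Rg <- frame_of(c(0, 0, 1), reference_field)
  R <- Rg %*% t(Rb)   # body -> global
  w <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
  if (w > 1e-6) {
    q <- c((R[3, 2] - R[2, 3]), (R[1, 3] - R[3, 1]), (R[2, 1] - R[1, 2])) /
      (4 * w)
    quat_normalize(c(q, w))
  } else quat_identity()
}

#' Run the stochastic filter over a trace
#'
#' Initializes the orientation to the null quaternion (the global frame is
#' defined to coincide with the sensor frame during the initial static
#' posture) and the reference magnetic field to the magnetometer mean over
#' the initial static window, then alternates prediction and gated updates
#' over the whole trace. If the trace does not begin with a static window,
#' the initial quaternion falls back to an accelerometer/magnetometer
#' TRIAD-style fix (with a warning) and the supplied `reference_field`
#' must be given.
#'
#' @param trace a [mimu_trace()] (bias-corrected gyro recommended).
#' @param params an [sf_params()].
#' @param init_window two-element numeric, start/end (s) of the static
#'   initialization window (default `c(0.5, 4.5)` within the 5 s prologue).
#' @param reference_field optional GGF reference field, uT; default is the
#'   static-window magnetometer mean (sensor and global frames coincide
#'   during the prologue).
#' @param q0 initial quaternion (default identity).
#' @param init_state optional [sf_state()] overriding the default initial
#'   state (and its covariance); `q0` is ignored when given.
#' @return An [orientation_series()]; the final [sf_state()] and the update
#'   acceptance rates are attached as attributes `state` and
#'   `acceptance`.
#' @export
sf_estimator <- function(trace, params = sf_params("manual"),
                         init_window = c(0.5, 4.5),
                         reference_field = NULL, q0 = quat_identity(),
                         init_state = NULL) {
  stopifnot(inherits(trace, "mimu_trace"), inherits(params, "sf_params"))
  n <- length(trace$time)
  if (n < 2L) stop("trace too short")
  win <- trace$time >= init_window[1L] & trace$time <= init_window[2L]
  static_start <- sum(win) >= 2L &&
    all(apply(trace$gyro[win, , drop = FALSE], 2L, stats::sd) <=
          3 * params$gyro_sd)
  if (static_start) {
    if (is.null(reference_field))
      reference_field <- colMeans(trace$mag[win, , drop = FALSE])
  } else {
    if (is.null(reference_field))
      stop("no static initialization window found; supply 'reference_field'")
    warning("no static prologue detected; initializing from an ",
            "accelerometer/magnetometer TRIAD fix")
    q0 <- triad_init(colMeans(trace$accel[seq_len(min(n, 16L)), , drop = FALSE]),
                     colMeans(trace$mag[seq_len(min(n, 16L)), , drop = FALSE]),
                     reference_field)
  }

  state <- if (is.null(init_state)) sf_state(q = q0) else init_state
  Q <- matrix(0, n, 4L)
  Q[1L, ] <- state$q
  n_acc <- 0L; n_mag <- 0L
  for (k in seq_len(n - 1L)) {
    dt <- trace$time[k + 1L] - trace$time[k]
    state <- sf_predict(state, trace$gyro[k, ], dt, params)
    state <- sf_update(state, trace$accel[k + 1L, ], trace$mag[k + 1L, ],
                       params, reference_field)
    acc <- attr(state, "accepted")
    n_acc <- n_acc + acc[1L]; n_mag <- n_mag + acc[2L]
    Q[k + 1L, ] <- state$q
  }
  if (n_acc + n_mag == 0L)
    warning("every aiding measurement was gated out: ",
            "the filter degraded to pure gyro integration")
  out <- orientation_series(trace$time, Q)
  attr(out, "state") <- state
  attr(out, "acceptance") <- c(accel = n_acc, mag = n_mag) / (n - 1L)
  out
}
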