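#' Ground-truth rigid-body motion
#'
#' Reference orientation of a moving MIMU together with the exact body-frame
#' angular velocity, the inertial (non-gravitational) acceleration, the
#' additive magnetic disturbance expressed in the global frame, and a
#' static-phase mask. Produced by the scenario generators and consumed by
#' [synthesize_trace()] and by the accuracy-assessment functions.
#'
#' @param orientation an [orientation_series()] (ULF-to-GGF).
#' @param omega n x 3 matrix, true angular velocity in deg/s (body frame).
#' @param accel_inertial n x 3 matrix, inertial acceleration in g (body frame).
#' @param mag_disturbance n x 3 matrix, additive field disturbance in uT (GGF).
#' @param static_mask logical vector, TRUE where the unit is stationary by
#'   construction.
#' @param sample_rate samples per second.
#' @param meta list of provenance metadata.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(orientation, omega, accel_inertial, mag_disturbance,
                         static_mask, sample_rate, meta = list()) {
  stopifnot(inherits(orientation, "orientation_series"))
  n <- length(orientation$time)
  omega <- as.matrix(omega)
  accel_inertial <- as.matrix(accel_inertial)
  mag_disturbance <- as.matrix(mag_disturbance)
  if (nrow(omega) != n || nrow(accel_inertial) != n ||
      nrow(mag_disturbance) != n || length(static_mask) != n)
    stop("all ground-truth series must share the orientation length")
  structure(list(orientation = orientation, omega = omega,
                 accel_inertial = accel_inertial,
                 mag_disturbance = mag_disturbance,
                 static_mask = static_mask, sample_rate = sample_rate,
                 events = list(), meta = meta),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: %d samples at %g samples/s, %.0f%% static\n",
              if (is.null(x$meta$scenario)) "motion" else x$meta$scenario,
              length(x$orientation$time), x$sample_rate,
              100 * mean(x$static_mask)))
  invisible(x)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

# a ⊗ B for fixed quaternion a and n x 4 matrix B, rowwise, renormalized
qmul_rows <- function(a, B) {
  av1 <- a[1L]; av2 <- a[2L]; av3 <- a[3L]; as <- a[4L]
  bx <- B[, 1L]; by <- B[, 2L]; bz <- B[, 3L]; bw <- B[, 4L]
  x <- as * bx + bw * av1 + av2 * bz - av3 * by
  y <- as * by + bw * av2 + av3 * bx - av1 * bz
  z <- as * bz + bw * av3 + av1 * by - av2 * bx
  w <- as * bw - av1 * bx - av2 * by - av3 * bz
  out <- cbind(x, y, z, w)
  out / sqrt(rowSums(out^2))
}

# rotate global-frame rows V (n x 3) into the body frame of quaternions Q
# (n x 4, ULF-to-GGF): rows of t(R(q_i)) %*% v_i
rotate_global_to_body <- function(Q, V) {
  qx <- -Q[, 1L]; qy <- -Q[, 2L]; qz <- -Q[, 3L]; w <- Q[, 4L]  # conjugate
  vx <- V[, 1L]; vy <- V[, 2L]; vz <- V[, 3L]
  tx <- 2 * (qy * vz - qz * vy)
  ty <- 2 * (qz * vx - qx * vz)
  tz <- 2 * (qx * vy - qy * vx)
  cbind(vx + w * tx + qy * tz - qz * ty,
        vy + w * ty + qz * tx - qx * tz,
        vz + w * tz + qx * ty - qy * tx)
}

# quintic smoothstep and its derivative (C2 ramp on [0, 1])
smootherstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u^3 * (10 - 15 * u + 6 * u^2)
}
smootherstep_deriv <- function(u) {
  inside <- u > 0 & u < 1
  out <- numeric(length(u))
  uu <- pmin(1, pmax(0, u))
  out[inside] <- (30 * uu^2 * (1 - uu)^2)[inside]
  out
}

#' Synthetic manual-routine ground truth
#'
#' Emulates a seated sequence of daily manual sub-tasks recorded by a
#' forearm-worn unit: a 5 s static prologue, then smooth (minimum-jerk)
#' rotations about each of the three sensor axes in turn, separated by
#' static pauses of at least two seconds, with small inertial-acceleration
#' bursts during the movements. Per-axis cumulative rotation is about 120
#' degrees (within +-20%). The schedule and amplitudes are randomized per
#' seed; identical seeds reproduce the output bit-for-bit.
#'
#' @param duration trial duration in seconds (default 60).
#' @param seed integer RNG seed.
#' @param sample_rate samples per second (default 128).
#' @param prologue leading static posture duration, s.
#' @param segment_angle nominal per-segment rotation amplitude, degrees; two
#'   segments per axis give the ~120 degree per-axis total.
#' @param angle_jitter relative amplitude jitter (uniform +-).
#' @param segment_time nominal movement duration per segment, s.
#' @param pause_time nominal static pause between segments, s (>= 2 s after
#'   jitter).
#' @param inertial_amp peak inertial acceleration during movements, g.
#' @return A [ground_truth()] object.
#' @export
make_manual_routine <- function(duration = 60, seed = 1, sample_rate = 128,
                                prologue = 5, segment_angle = 60,
                                angle_jitter = 0.15, segment_time = 4,
                                pause_time = 2.5, inertial_amp = 0.1) {
  if (duration <= prologue) stop("duration too short for the static prologue")
  with_seed(seed, {
    n_cycles <- 2L
    axes_order <- unlist(lapply(seq_len(n_cycles), function(i) sample(1:3)))
    n_seg <- length(axes_order)
    amp <- segment_angle * stats::runif(n_seg, 1 - angle_jitter, 1 + angle_jitter) *
      sample(c(-1, 1), n_seg, replace = TRUE)
    t_move <- segment_time * stats::runif(n_seg, 0.9, 1.1)
    t_pause <- pause_time * stats::runif(n_seg, 0.8, 1.2)
    a_dir <- matrix(stats::rnorm(3L * n_seg), ncol = 3L)
    a_dir <- a_dir / sqrt(rowSums(a_dir^2))
    schedule_len <- prologue + sum(t_move + t_pause)
    if (duration < schedule_len)
      stop(sprintf("duration %.1f s too short for the task schedule (%.1f s)",
                   duration, schedule_len))

    n <- round(duration * sample_rate)
    tt <- (seq_len(n) - 1L) / sample_rate
    Q <- matrix(rep(quat_identity(), each = n), ncol = 4L)
    omega <- matrix(0, n, 3L)
    a_in <- matrix(0, n, 3L)
    static <- rep(TRUE, n)

    q_seg <- quat_identity()
    t_cursor <- prologue
    for (k in seq_len(n_seg)) {
      i0 <- which(tt >= t_cursor & tt < t_cursor + t_move[k])
      u <- (tt[i0] - t_cursor) / t_move[k]
      theta <- amp[k] * pi / 180 * smootherstep(u)
      theta_dot <- amp[k] * pi / 180 * smootherstep_deriv(u) / t_move[k]
      axis <- c(0, 0, 0); axis[axes_order[k]] <- 1
      dq <- cbind(outer(sin(theta / 2), axis), cos(theta / 2))
      Q[i0, ] <- qmul_rows(q_seg, dq)
      omega[i0, axes_order[k]] <- theta_dot * 180 / pi
      burst <- inertial_amp * sin(pi * u)^2 * sin(4 * pi * u)
      a_in[i0, ] <- outer(burst, a_dir[k, ])
      static[i0] <- FALSE
      q_seg <- quat_multiply(q_seg, quat_from_axis_angle(axis, amp[k] * pi / 180))
      # remainder of the trial keeps the reached orientation
      i1 <- which(tt >= t_cursor + t_move[k])
      Q[i1, ] <- matrix(rep(q_seg, each = length(i1)), ncol = 4L)
      t_cursor <- t_cursor + t_move[k] + t_pause[k]
    }

    ground_truth(orientation_series(tt, Q),
                 omega, a_in, matrix(0, n, 3L), static, sample_rate,
                 meta = list(scenario = "manual_routine", seed = seed,
                             axis_totals = vapply(1:3, function(a)
                               sum(abs(amp[axes_order == a])), numeric(1))))
  })
}

#' Synthetic figure-of-eight locomotion ground truth
#'
#' Emulates walking along a figure-of-eight pathway with a unit on the lower
#' trunk: after a 5 s static prologue and a smooth 3 s ramp-in, the heading
#' oscillates through alternating left/right turns with a total excursion of
#' about 260 degrees, while roll and pitch oscillate a few degrees at gait
#' frequencies; there are no static phases after the prologue. The
#' vertical-axis angular velocity is about 3.6 times that of the other two
#' axes, and a cyclic inertial acceleration emulates the gait. A slow
#' additive magnetic field variation (vertically dominant, amplitude
#' `field_variation_amp`) emulates the spatial inhomogeneity sampled along
#' the walking path.
#'
#' @param duration trial duration in seconds (default 180).
#' @param seed integer RNG seed.
#' @param sample_rate samples per second (default 128).
#' @param prologue leading static posture, s.
#' @param ramp duration of the smooth transition from standing to walking, s.
#' @param heading_amp heading oscillation amplitude, degrees (excursion is
#'   twice this value).
#' @param heading_period figure-of-eight lap period, s.
#' @param amp_jitter relative jitter on oscillation amplitudes (uniform +-).
#' @param roll_amp,roll_freq roll oscillation amplitude (deg) and
#'   frequency (Hz, stride rate).
#' @param pitch_amp,pitch_freq pitch oscillation amplitude (deg) and
#'   frequency (Hz, step rate).
#' @param inertial_amp peak gait inertial acceleration, g.
#' @param field_variation_amp peak magnitude of the slow magnetic field
#'   variation along the path, uT.
#' @return A [ground_truth()] object.
#' @export
make_locomotion <- function(duration = 180, seed = 1, sample_rate = 128,
                            prologue = 5, ramp = 3, heading_amp = 130,
                            heading_period = 14, amp_jitter = 0.03,
                            roll_amp = 2.5, roll_freq = 0.9,
                            pitch_amp = 1.5, pitch_freq = 1.8,
                            inertial_amp = 0.15, field_variation_amp = 5) {
  if (duration <= prologue + ramp)
    stop("duration too short for the static prologue and ramp")
  with_seed(seed, {
    jit <- function() stats::runif(1, 1 - amp_jitter, 1 + amp_jitter)
    A_psi <- heading_amp * jit() * pi / 180
    A_th <- pitch_amp * jit() * pi / 180
    A_ph <- roll_amp * jit() * pi / 180
    ph_th <- stats::runif(1, 0, 2 * pi)
    ph_ph <- stats::runif(1, 0, 2 * pi)
    ph_d <- stats::runif(3, 0, 2 * pi)

    n <- round(duration * sample_rate)
    tt <- (seq_len(n) - 1L) / sample_rate
    tau <- pmax(0, tt - prologue)
    e <- smootherstep(tau / ramp)
    e_dot <- smootherstep_deriv(tau / ramp) / ramp

    w_psi <- 2 * pi / heading_period
    w_th <- 2 * pi * pitch_freq
    w_ph <- 2 * pi * roll_freq
    psi <- e * A_psi * sin(w_psi * tau)
    th <- e * A_th * sin(w_th * tau + ph_th)
    ph <- e * A_ph * sin(w_ph * tau + ph_ph)
    psi_dot <- e_dot * A_psi * sin(w_psi * tau) + e * A_psi * w_psi * cos(w_psi * tau)
    th_dot <- e_dot * A_th * sin(w_th * tau + ph_th) +
      e * A_th * w_th * cos(w_th * tau + ph_th)
    ph_dot <- e_dot * A_ph * sin(w_ph * tau + ph_ph) +
      e * A_ph * w_ph * cos(w_ph * tau + ph_ph)

    # body rates for the Z-Y-X (yaw-pitch-roll) sequence
    wx <- ph_dot - psi_dot * sin(th)
    wy <- th_dot * cos(ph) + psi_dot * cos(th) * sin(ph)
    wz <- psi_dot * cos(th) * cos(ph) - th_dot * sin(ph)
    omega <- cbind(wx, wy, wz) * 180 / pi

    cy <- cos(psi / 2); sy <- sin(psi / 2)
    cp <- cos(th / 2); sp <- sin(th / 2)
    cr <- cos(ph / 2); sr <- sin(ph / 2)
    Q <- cbind(cy * cp * sr - sy * sp * cr,
               cy * sp * cr + sy * cp * sr,
               sy * cp * cr - cy * sp * sr,
               cy * cp * cr + sy * sp * sr)

    # gait inertial acceleration, body frame: vertical bounce at step rate
    # plus a smaller fore-aft component at stride rate
    a_in <- cbind(0.4 * inertial_amp * e * sin(w_ph * tau + ph_ph + pi / 3),
                  0,
                  inertial_amp * e * sin(w_th * tau + ph_th))

    # slow spatial field variation sampled along the periodic path,
    # vertically dominant (indoor anomalies), peak |d| <= field_variation_amp
    wgt <- c(0.35, 0.35, 0.87)
    periods <- heading_period * c(2, 3, 5)
    d <- sapply(1:3, function(i)
      field_variation_amp * wgt[i] * e * sin(2 * pi * tau / periods[i] + ph_d[i]))

    ground_truth(orientation_series(tt, Q),
                 omega, a_in, d, tt < prologue, sample_rate,
                 meta = list(scenario = "locomotion", seed = seed))
  })
}

#' Add a transient ferromagnetic disturbance (magnet event)
#'
#' Superimposes a smooth bell-shaped disturbance on the magnetic field of a
#' ground-truth object (in GGF coordinates) or directly on the magnetometer
#' columns of a measured trace (sensor coordinates). The temporal profile
#' follows the sharp inverse-cube rise and fall of a dipole source being
#' approached and withdrawn: `(1 + (t'/s)^2)^(-3/2)` with `s` chosen so the
#' magnitude at the window edges is below 1% of the peak, tapered to exactly
#' zero at the edges. Outside the window the field is untouched.
#'
#' @param x a [ground_truth()] or [mimu_trace()] object.
#' @param start event window start, s.
#' @param duration event window length, s.
#' @param peak peak disturbance magnitude, uT (>= 0).
#' @param direction 3-vector disturbance direction (GGF for ground truth,
#'   sensor frame for a trace); normalized internally.
#' @return The modified object; events may not overlap.
#' @export
add_magnet_event <- function(x, start, duration, peak,
                             direction = c(1, 1, 1)) {
  if (peak < 0) stop("'peak' must be >= 0")
  if (duration <= 0) stop("'duration' must be positive")
  tt <- if (inherits(x, "ground_truth")) x$orientation$time
  else if (inherits(x, "mimu_trace")) x$time
  else stop("'x' must be a ground_truth or mimu_trace")
  if (start < tt[1L] || start + duration > tt[length(tt)])
    stop("event window falls outside the trace")
  for (ev in x$events)
    if (start < ev$start + ev$duration && ev$start < start + duration)
      stop("overlapping magnet events are not supported; keep events separable")
  direction <- direction / sqrt(sum(direction^2))
  centre <- start + duration / 2
  s <- (duration / 2) / 4.7
  u <- (tt - centre) / s
  prof <- (1 + u^2)^(-1.5)
  inside <- tt >= start & tt <= start + duration
  prof[!inside] <- 0
  # cosine taper over the outer 10% of the window forces exact zeros at edges
  edge <- pmin(1, pmax(0, (duration / 2 - abs(tt - centre)) / (0.1 * duration)))
  prof <- prof * smootherstep(edge)
  add <- peak * outer(prof, direction)
  if (inherits(x, "ground_truth")) {
    x$mag_disturbance <- x$mag_disturbance + add
  } else {
    x$mag <- clip_range(x$mag + add, 600)
  }
  x$events <- c(x$events, list(list(start = start, duration = duration,
                                    peak = peak)))
  x
}

#' Synthesize MIMU measurements from ground truth
#'
#' Applies the sensor error model to an ideal motion: the gyroscope reads the
#' true body rate plus a constant bias, an optional bias random walk and
#' white noise; the accelerometer reads the specific force (rotated gravity
#' reaction plus inertial acceleration) with white noise; the magnetometer
#' reads the per-axis scaled, hard-iron-shifted body-frame projection of the
#' reference field plus any disturbance, with white noise. All streams are
#' clipped at the unit's full-scale ranges.
#'
#' @param truth a [ground_truth()] object.
#' @param model a [sensor_model()].
#' @param seed integer RNG seed (recorded in the trace metadata).
#' @return A [mimu_trace()].
#' @export
synthesize_trace <- function(truth, model, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(model, "sensor_model"))
  n <- length(truth$orientation$time)
  dt <- 1 / truth$sample_rate
  with_seed(seed, {
    bias <- matrix(model$gyro_bias, n, 3L, byrow = TRUE)
    if (model$gyro_bias_walk_sd > 0) {
      steps <- matrix(stats::rnorm(3L * n, sd = model$gyro_bias_walk_sd * dt),
                      n, 3L)
      bias <- bias + apply(steps, 2L, cumsum)
    }
    gyro <- truth$omega + bias +
      matrix(stats::rnorm(3L * n, sd = model$gyro_noise_sd), n, 3L)

    Q <- truth$orientation$quat
    grav_body <- rotate_global_to_body(Q, matrix(c(0, 0, -1), n, 3L, byrow = TRUE))
    accel <- grav_body + truth$accel_inertial +
      matrix(stats::rnorm(3L * n, sd = model$accel_noise_sd), n, 3L)

    field_global <- matrix(model$reference_field, n, 3L, byrow = TRUE) +
      truth$mag_disturbance
    mag_body <- rotate_global_to_body(Q, field_global)
    mag <- sweep(mag_body, 2L, model$mag_sensitivity, `*`) +
      matrix(model$mag_hard_iron, n, 3L, byrow = TRUE) +
      matrix(stats::rnorm(3L * n, sd = model$mag_noise_sd), n, 3L)

    mimu_trace(truth$orientation$time, gyro, accel, mag,
               sample_rate = truth$sample_rate,
               meta = c(truth$meta, list(synth_seed = seed)))
  })
}

#' Synthesize a stationary calibration acquisition
#'
#' The unit rests on a table in the identity orientation; only sensor errors
#' drive the measurements. Used for gyro bias estimation and for the static
#' accelerometer check.
#'
#' @param duration acquisition length in seconds (default 60, the standard
#'   one-minute table acquisition).
#' @param model a [sensor_model()].
#' @param seed integer RNG seed.
#' @param orientation optional unit quaternion giving the resting attitude
#'   (default identity).
#' @return A [mimu_trace()].
#' @export
make_static_trace <- function(duration = 60, model = sensor_model(), seed = 1,
                              orientation = quat_identity()) {
  n <- round(duration * model$sample_rate)
  tt <- (seq_len(n) - 1L) / model$sample_rate
  Q <- matrix(rep(quat_normalize(orientation), each = n), ncol = 4L)
  truth <- ground_truth(orientation_series(tt, Q),
                        matrix(0, n, 3L), matrix(0, n, 3L), matrix(0, n, 3L),
                        rep(TRUE, n), model$sample_rate,
                        meta = list(scenario = "static", seed = seed))
  synthesize_trace(truth, model, seed = seed)
}
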