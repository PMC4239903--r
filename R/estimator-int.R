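#' Orientation by numerical integration of the quaternion kinematic equation
#'
#' The INT estimator: sample-by-sample exact propagation of the quaternion
#' kinematic differential equation under the piecewise-constant angular
#' velocity assumption, driven by the (bias-corrected) gyroscope stream
#' alone. The initial condition defaults to the null unit quaternion, the
#' global frame being defined to coincide with the sensor frame during the
#' initial static posture.
#'
#' @param trace a [mimu_trace()]; only the gyro stream (deg/s) is used.
#'   Subtract the static bias with [correct_gyro_bias()] beforehand.
#' @param q0 initial unit quaternion (default identity).
#' @return An [orientation_series()] in the ULF-to-GGF convention.
#' @export
int_estimator <- function(trace, q0 = quat_identity()) {
  stopifnot(inherits(trace, "mimu_trace"))
  n <- length(trace$time)
  if (n < 2L) stop("trace too short to integrate")
  gyro_rad <- trace$gyro * pi / 180
  Q <- matrix(0, n, 4L)
  q <- quat_normalize(q0)
  Q[1L, ] <- q
  tt <- trace$time
  for (k in seq_len(n - 1L)) {
    q <- integrate_step(q, gyro_rad[k, ], tt[k + 1L] - tt[k])
    Q[k + 1L, ] <- q
  }
  orientation_series(tt, Q)
}

#' Naive per-component integration of the angular velocity
#'
#' Cumulative trapezoidal integration of each gyroscope axis independently,
#' in degrees. This is the common shortcut of integrating the angular
#' velocity components separately: the result is NOT an orientation
#' estimate and the three angle series are not Euler angles — the
#' orientation information linking the local and global frames at each
#' instant is discarded. Provided to demonstrate how far this shortcut
#' diverges from the kinematic-equation integration whenever the motion is
#' not planar.
#'
#' @param trace a [mimu_trace()].
#' @return n x 3 matrix of per-axis integrated angles in degrees.
#' @export
naive_component_integration <- function(trace) {
  stopifnot(inherits(trace, "mimu_trace"))
  out <- apply(trace$gyro, 2L, function(col)
    pracma::cumtrapz(trace$time, col))
  colnames(out) <- c("x", "y", "z")
  out
}
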