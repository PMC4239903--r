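#' Quaternion algebra for rigid-body orientation
#'
#' Quaternions are stored as plain numeric vectors of length 4 in scalar-last
#' order `c(x, y, z, w)`: vector part first, scalar part last, so the identity
#' (null) rotation is `c(0, 0, 0, 1)`. The Hamilton product convention is
#' used throughout. A quaternion `q` represents the orientation of the unit
#' local frame (ULF) with respect to the gravity-aligned global frame (GGF):
#' `quat_rotate(q, v)` maps ULF coordinates of a vector into GGF coordinates.
#'
#' @name quaternion
#' @keywords internal
NULL

#' Identity quaternion
#'
#' @return The null unit quaternion `c(0, 0, 0, 1)`.
#' @export
quat_identity <- function() c(0, 0, 0, 1)

check_quat <- function(q, arg = "q") {
  if (!is.numeric(q) || length(q) != 4L || any(!is.finite(q)))
    stop(sprintf("'%s' must be a finite numeric quaternion of length 4", arg))
  invisible(q)
}

#' Normalize a quaternion to unit norm
#'
#' @param q numeric length-4 quaternion, scalar last.
#' @return Unit-norm quaternion.
#' @export
quat_normalize <- function(q) {
  check_quat(q)
  n <- sqrt(sum(q * q))
  if (n < .Machine$double.eps)
    stop("cannot normalize a zero quaternion")
  q / n
}

#' Quaternion conjugate
#'
#' For a unit quaternion the conjugate is the inverse rotation.
#'
#' @param q numeric length-4 quaternion, scalar last.
#' @return Conjugate quaternion `c(-x, -y, -z, w)`.
#' @export
quat_conjugate <- function(q) {
  check_quat(q)
  c(-q[1L], -q[2L], -q[3L], q[4L])
}

#' Hamilton product of two quaternions
#'
#' Computes `a %*% b` under the scalar-last Hamilton convention and
#' renormalizes the result to guard against floating-point norm drift.
#' Composition order matches rotation composition: if `a` rotates frame B
#' into A and `b` rotates C into B, then `quat_multiply(a, b)` rotates C
#' into A.
#'
#' @param a,b numeric length-4 quaternions, scalar last, unit norm.
#' @return Unit-norm product quaternion.
#' @export
quat_multiply <- function(a, b) {
  check_quat(a, "a"); check_quat(b, "b")
  av <- a[1:3]; as <- a[4L]
  bv <- b[1:3]; bs <- b[4L]
  v <- as * bv + bs * av + c(
    av[2L] * bv[3L] - av[3L] * bv[2L],
    av[3L] * bv[1L] - av[1L] * bv[3L],
    av[1L] * bv[2L] - av[2L] * bv[1L])
  s <- as * bs - sum(av * bv)
  quat_normalize(c(v, s))
}

#' Quaternion from axis-angle
#'
#' @param axis unit 3-vector rotation axis.
#' @param angle rotation angle in radians.
#' @return Unit quaternion `c(axis * sin(angle/2), cos(angle/2))`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  if (!is.numeric(axis) || length(axis) != 3L || any(!is.finite(axis)))
    stop("'axis' must be a finite numeric 3-vector")
  if (!is.finite(angle)) stop("'angle' must be finite")
  n <- sqrt(sum(axis * axis))
  if (n < .Machine$double.eps) stop("'axis' must be non-zero")
  axis <- axis / n
  c(axis * sin(angle / 2), cos(angle / 2))
}

#' Axis-angle from quaternion
#'
#' Returns the rotation axis and angle in `(0, pi]`; for the identity
#' rotation the angle is 0 and the axis defaults to the z axis.
#'
#' @param q unit quaternion, scalar last.
#' @return List with elements `axis` (unit 3-vector) and `angle` (radians).
#' @export
quat_to_axis_angle <- function(q) {
  q <- quat_normalize(q)
  if (q[4L] < 0) q <- -q   # canonical hemisphere: angle in [0, pi]
  sin_half <- sqrt(sum(q[1:3]^2))
  angle <- 2 * atan2(sin_half, q[4L])
  axis <- if (sin_half < 1e-12) c(0, 0, 1) else q[1:3] / sin_half
  list(axis = axis, angle = angle)
}

#' Rotation angle of a quaternion
#'
#' The geodesic rotation angle `2*acos(|w|)` in radians, insensitive to the
#' quaternion double cover (q and -q encode the same rotation).
#'
#' @param q unit quaternion, scalar last.
#' @return Angle in radians, in `[0, pi]`.
#' @export
quat_angle <- function(q) {
  q <- quat_normalize(q)
  2 * acos(min(1, abs(q[4L])))
}

#' Rotation matrix of a quaternion
#'
#' @param q unit quaternion, scalar last, mapping local to global frame.
#' @return 3x3 rotation matrix `R` with `R %*% v_local = v_global`.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  x <- q[1L]; y <- q[2L]; z <- q[3L]; w <- q[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)),
    nrow = 3L, byrow = TRUE)
}

#' Rotate a vector by a quaternion
#'
#' @param q unit quaternion, scalar last (ULF-to-GGF).
#' @param v numeric 3-vector in the local frame.
#' @return The vector expressed in the global frame.
#' @export
quat_rotate <- function(q, v) {
  q <- quat_normalize(q)
  qv <- q[1:3]; w <- q[4L]
  t2 <- 2 * c(qv[2L] * v[3L] - qv[3L] * v[2L],
              qv[3L] * v[1L] - qv[1L] * v[3L],
              qv[1L] * v[2L] - qv[2L] * v[1L])
  v + w * t2 + c(qv[2L] * t2[3L] - qv[3L] * t2[2L],
                 qv[3L] * t2[1L] - qv[1L] * t2[3L],
                 qv[1L] * t2[2L] - qv[2L] * t2[1L])
}

#' Kinematic matrix of the quaternion differential equation
#'
#' Builds the 4x4 skew-symmetric matrix `Omega(omega)` of the quaternion
#' kinematic differential equation `dq/dt = 0.5 * Omega(omega) %*% q`, laid
#' out as `[[-skew(omega), omega], [-t(omega), 0]]` for a scalar-last
#' quaternion. Under the Hamilton convention this is the matrix of
#' right-multiplication by the pure quaternion `c(omega, 0)`, so the
#' equation propagates the ULF-to-GGF quaternion driven by the body-frame
#' angular velocity.
#'
#' @param omega angular velocity 3-vector in rad/s, body (ULF) frame.
#' @return 4x4 skew-symmetric matrix.
#' @export
omega_matrix <- function(omega) {
  if (!is.numeric(omega) || length(omega) != 3L || any(!is.finite(omega)))
    stop("'omega' must be a finite numeric 3-vector")
  wx <- omega[1L]; wy <- omega[2L]; wz <- omega[3L]
  matrix(c(
    0,  wz, -wy, wx,
    -wz, 0,  wx, wy,
    wy, -wx, 0,  wz,
    -wx, -wy, -wz, 0), nrow = 4L, byrow = TRUE)
}

#' Exact one-step quaternion propagation under constant angular velocity
#'
#' Propagates the orientation over a time step assuming the angular velocity
#' is constant within the step, i.e. the closed-form matrix exponential of
#' `0.5 * Omega(omega) * dt`: a rotation of `|omega| * dt` radians about
#' `omega / |omega|` applied in the body frame.
#'
#' @param q unit quaternion (ULF-to-GGF), scalar last.
#' @param omega angular velocity 3-vector in rad/s, body frame.
#' @param dt time step in seconds, positive.
#' @return Unit quaternion after the step; `q` unchanged when `omega` is zero.
#' @export
integrate_step <- function(q, omega, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive scalar")
  if (!is.numeric(omega) || length(omega) != 3L || any(!is.finite(omega)))
    stop("'omega' must be a finite numeric 3-vector")
  n <- sqrt(sum(omega * omega))
  if (n * dt < 1e-14) return(quat_normalize(q))
  half <- n * dt / 2
  dq <- c(omega / n * sin(half), cos(half))
  quat_multiply(q, dq)
}

#' Quaternion from aerospace (yaw-pitch-roll) Euler angles
#'
#' Z-Y-X intrinsic rotation sequence: yaw about the global down axis, then
#' pitch, then roll. Angles in degrees, consistent with the GGF convention
#' (X forward, Y right, Z down).
#'
#' @param yaw,pitch,roll angles in degrees.
#' @return Unit quaternion, ULF-to-GGF, scalar last.
#' @export
quat_from_euler <- function(yaw, pitch, roll) {
  y <- yaw * pi / 180; p <- pitch * pi / 180; r <- roll * pi / 180
  quat_multiply(
    quat_multiply(quat_from_axis_angle(c(0, 0, 1), y),
                  quat_from_axis_angle(c(0, 1, 0), p)),
    quat_from_axis_angle(c(1, 0, 0), r))
}

#' Euler angles (yaw-pitch-roll, degrees) from a quaternion
#'
#' Inverse of [quat_from_euler()] (Z-Y-X sequence, GGF with Z down).
#'
#' @param q unit quaternion, ULF-to-GGF, scalar last.
#' @return Named numeric vector `c(yaw, pitch, roll)` in degrees.
#' @export
quat_to_euler <- function(q) {
  q <- quat_normalize(q)
  x <- q[1L]; y <- q[2L]; z <- q[3L]; w <- q[4L]
  yaw <- atan2(2 * (x * y + w * z), 1 - 2 * (y * y + z * z))
  sp <- -2 * (x * z - w * y)
  pitch <- asin(max(-1, min(1, sp)))
  roll <- atan2(2 * (y * z + w * x), 1 - 2 * (x * x + y * y))
  c(yaw = yaw, pitch = pitch, roll = roll) * 180 / pi
}

# right-multiplication matrix: quat_multiply(q, p) == mat_right(p) %*% q
# (without the renormalization)
mat_right <- function(p) {
  pv <- p[1:3]; ps <- p[4L]
  rbind(cbind(ps * diag(3) - skew3(pv), pv), c(-pv, ps))
}

# 4x3 map: q ⊗ [delta; 0] = xi_mat(q) %*% delta (pure-vector right factor)
xi_mat <- function(q) {
  qv <- q[1:3]; w <- q[4L]
  rbind(w * diag(3) + skew3(qv), -qv)
}

skew3 <- function(v) {
  matrix(c(0, -v[3L], v[2L],
           v[3L], 0, -v[1L],
           -v[2L], v[1L], 0), nrow = 3L, byrow = TRUE)
}

# Jacobian of h(q) = t(R(q)) %*% v (global vector v seen in the body frame)
# with respect to the four quaternion components, differentiating the
# quadratic-form rotation matrix; 3x4.
d_rt_v_dq <- function(q, v) {
  x <- q[1L]; y <- q[2L]; z <- q[3L]; w <- q[4L]
  v1 <- v[1L]; v2 <- v[2L]; v3 <- v[3L]
  2 * matrix(c(
    v2 * y + v3 * z, -2 * v1 * y + v2 * x - v3 * w,
    -2 * v1 * z + v2 * w + v3 * x, v2 * z - v3 * y,
    v1 * y - 2 * v2 * x + v3 * w, v1 * x + v3 * z,
    -v1 * w - 2 * v2 * z + v3 * y, -v1 * z + v3 * x,
    v1 * z - v2 * w - 2 * v3 * x, v1 * w + v2 * z - 2 * v3 * y,
    v1 * x + v2 * y, v1 * y - v2 * x),
    nrow = 3L, byrow = TRUE)
}
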