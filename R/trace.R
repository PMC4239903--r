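#' MIMU measurement trace
#'
#' Container for uniformly sampled tri-axial gyroscope, accelerometer and
#' magnetometer streams. Units follow the device datasheet convention:
#' angular velocity in deg/s, specific force in g, magnetic field in
#' microtesla (uT). Values are clipped to the full-scale ranges of the
#' emulated unit (+-1500 deg/s, +-6 g, +-600 uT).
#'
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param gyro n x 3 matrix, angular velocity in deg/s (ULF axes).
#' @param accel n x 3 matrix, specific force in g.
#' @param mag n x 3 matrix, magnetic field in uT.
#' @param sample_rate samples per second.
#' @param meta optional list of provenance metadata (scenario tag, seed, ...).
#' @return Object of class `mimu_trace`.
#' @export
mimu_trace <- function(time, gyro, accel, mag, sample_rate, meta = list()) {
  gyro <- as.matrix(gyro); accel <- as.matrix(accel); mag <- as.matrix(mag)
  n <- length(time)
  if (n < 1L) stop("empty trace")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  for (nm in c("gyro", "accel", "mag")) {
    m <- get(nm)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3L)
      stop(sprintf("'%s' must be an n x 3 matrix matching 'time'", nm))
    if (any(!is.finite(m))) stop(sprintf("non-finite values in '%s'", nm))
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("'sample_rate' must be positive")
  gyro <- clip_range(gyro, 1500)
  accel <- clip_range(accel, 6)
  mag <- clip_range(mag, 600)
  structure(list(time = time, gyro = gyro, accel = accel, mag = mag,
                 sample_rate = sample_rate, meta = meta),
            class = "mimu_trace")
}

clip_range <- function(m, full_scale) {
  m[m > full_scale] <- full_scale
  m[m < -full_scale] <- -full_scale
  m
}

#' @export
print.mimu_trace <- function(x, ...) {
  cat(sprintf("<mimu_trace> %d samples at %g samples/s (%.1f s)\n",
              length(x$time), x$sample_rate, diff(range(x$time))))
  if (!is.null(x$meta$scenario))
    cat(sprintf("  scenario: %s (seed %s)\n", x$meta$scenario,
                format(x$meta$seed)))
  invisible(x)
}

#' Orientation time series
#'
#' A sequence of unit quaternions with timestamps and an explicit frame
#' convention flag. The default convention `"ULF_to_GGF"` means each
#' quaternion maps ULF (sensor) coordinates into GGF (global) coordinates,
#' i.e. it is the orientation of the unit with respect to the global frame.
#'
#' @param time numeric vector of sample times in seconds.
#' @param quat n x 4 matrix of scalar-last quaternions (columns x, y, z, w).
#' @param frame `"ULF_to_GGF"` or `"GGF_to_ULF"`.
#' @return Object of class `orientation_series`.
#' @export
orientation_series <- function(time, quat,
                               frame = c("ULF_to_GGF", "GGF_to_ULF")) {
  frame <- match.arg(frame)
  quat <- as.matrix(quat)
  if (nrow(quat) != length(time) || ncol(quat) != 4L)
    stop("'quat' must be an n x 4 matrix matching 'time'")
  if (any(!is.finite(quat))) stop("non-finite quaternion values")
  nrm <- sqrt(rowSums(quat^2))
  if (any(abs(nrm - 1) > 1e-6)) quat <- quat / nrm
  colnames(quat) <- c("qx", "qy", "qz", "qw")
  structure(list(time = time, quat = quat, frame = frame),
            class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d samples (%.1f s), frame %s\n",
              length(x$time), diff(range(x$time)), x$frame))
  invisible(x)
}

#' Invert the frame convention of an orientation series
#'
#' Conjugates every quaternion and flips the frame flag.
#'
#' @param os an [orientation_series()].
#' @return The series expressed in the opposite convention.
#' @export
invert_frame <- function(os) {
  stopifnot(inherits(os, "orientation_series"))
  q <- os$quat
  q[, 1:3] <- -q[, 1:3]
  orientation_series(os$time, q,
                     frame = setdiff(c("ULF_to_GGF", "GGF_to_ULF"), os$frame))
}

#' Euler-angle view of an orientation series
#'
#' @param os an [orientation_series()] in the `"ULF_to_GGF"` convention.
#' @return n x 3 matrix of yaw, pitch, roll in degrees.
#' @export
orientation_euler <- function(os) {
  stopifnot(inherits(os, "orientation_series"))
  if (os$frame != "ULF_to_GGF") os <- invert_frame(os)
  ang <- t(apply(os$quat, 1L, quat_to_euler))
  colnames(ang) <- c("yaw", "pitch", "roll")
  ang
}

#' Sensor error model for synthetic MIMU measurements
#'
#' Holds the stochastic and deterministic error parameters used by
#' [synthesize_trace()]. Defaults follow the noise figures of the emulated
#' unit: gyro white noise 2.5 deg/s, accelerometer 0.01 g, magnetometer 3 uT,
#' and a homogeneous 40 uT reference field with a 60 degree downward dip
#' (GGF components c(20, 0, 34.64) uT, Z positive down).
#'
#' @param gyro_noise_sd gyro white-noise standard deviation, deg/s.
#' @param gyro_bias constant gyro bias 3-vector, deg/s.
#' @param gyro_bias_walk_sd gyro bias random-walk intensity, deg/s^2; each
#'   sample the bias is incremented by N(0, (walk_sd * dt)^2).
#' @param accel_noise_sd accelerometer white-noise SD, g.
#' @param mag_noise_sd magnetometer white-noise SD, uT.
#' @param mag_hard_iron additive magnetometer bias 3-vector, uT.
#' @param mag_sensitivity per-axis magnetometer scale factors (dimensionless).
#' @param reference_field local magnetic field 3-vector in GGF, uT.
#' @param sample_rate samples per second.
#' @return Object of class `sensor_model`.
#' @export
sensor_model <- function(gyro_noise_sd = 2.5,
                         gyro_bias = c(0, 0, 0),
                         gyro_bias_walk_sd = 0,
                         accel_noise_sd = 0.01,
                         mag_noise_sd = 3,
                         mag_hard_iron = c(0, 0, 0),
                         mag_sensitivity = c(1, 1, 1),
                         reference_field = c(20, 0, sqrt(40^2 - 20^2)),
                         sample_rate = 128) {
  if (any(c(gyro_noise_sd, accel_noise_sd, mag_noise_sd, gyro_bias_walk_sd) < 0))
    stop("noise standard deviations must be >= 0")
  if (sample_rate <= 0) stop("'sample_rate' must be positive")
  if (length(gyro_bias) != 3L || length(mag_hard_iron) != 3L ||
      length(mag_sensitivity) != 3L || length(reference_field) != 3L)
    stop("vector parameters must have length 3")
  if (any(mag_sensitivity <= 0)) stop("'mag_sensitivity' must be positive")
  structure(list(gyro_noise_sd = gyro_noise_sd, gyro_bias = gyro_bias,
                 gyro_bias_walk_sd = gyro_bias_walk_sd,
                 accel_noise_sd = accel_noise_sd, mag_noise_sd = mag_noise_sd,
                 mag_hard_iron = mag_hard_iron,
                 mag_sensitivity = mag_sensitivity,
                 reference_field = reference_field,
                 sample_rate = sample_rate),
            class = "sensor_model")
}

#' Write / read a MIMU trace as CSV
#'
#' Plain-text interchange format with header
#' `t,gx,gy,gz,ax,ay,az,mx,my,mz` (seconds, deg/s, g, uT) and `#`-prefixed
#' comment lines carrying the sample rate and metadata.
#'
#' @param trace a [mimu_trace()].
#' @param file path to the CSV file.
#' @return `read_mimu_csv` returns a [mimu_trace()];
#'   `write_mimu_csv` returns `file` invisibly.
#' @export
write_mimu_csv <- function(trace, file) {
  stopifnot(inherits(trace, "mimu_trace"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# mimu_trace sample_rate=%g", trace$sample_rate), con)
  if (!is.null(trace$meta$scenario))
    writeLines(sprintf("# scenario=%s seed=%s", trace$meta$scenario,
                       format(trace$meta$seed)), con)
  df <- data.frame(t = trace$time, gx = trace$gyro[, 1], gy = trace$gyro[, 2],
                   gz = trace$gyro[, 3], ax = trace$accel[, 1],
                   ay = trace$accel[, 2], az = trace$accel[, 3],
                   mx = trace$mag[, 1], my = trace$mag[, 2],
                   mz = trace$mag[, 3])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_mimu_csv
#' @export
read_mimu_csv <- function(file) {
  hdr <- readLines(file, n = 5L)
  rate_line <- grep("sample_rate=", hdr, value = TRUE)
  rate <- if (length(rate_line))
    as.numeric(sub(".*sample_rate=([0-9.eE+-]+).*", "\\1", rate_line[1L]))
  else NA_real_
  df <- utils::read.csv(file, comment.char = "#")
  if (is.na(rate)) rate <- 1 / stats::median(diff(df$t))
  mimu_trace(df$t, as.matrix(df[, c("gx", "gy", "gz")]),
             as.matrix(df[, c("ax", "ay", "az")]),
             as.matrix(df[, c("mx", "my", "mz")]), sample_rate = rate)
}

#' Write / read an orientation series as CSV
#'
#' Header `t,qx,qy,qz,qw`, scalar-last quaternions, with the frame
#' convention recorded in a `#` comment line.
#'
#' @param os an [orientation_series()].
#' @param file path to the CSV file.
#' @return `read_orientation_csv` returns an [orientation_series()];
#'   `write_orientation_csv` returns `file` invisibly.
#' @export
write_orientation_csv <- function(os, file) {
  stopifnot(inherits(os, "orientation_series"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# orientation_series frame=%s", os$frame), con)
  df <- data.frame(t = os$time, qx = os$quat[, 1], qy = os$quat[, 2],
                   qz = os$quat[, 3], qw = os$quat[, 4])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_orientation_csv
#' @export
read_orientation_csv <- function(file) {
  hdr <- readLines(file, n = 2L)
  frame_line <- grep("frame=", hdr, value = TRUE)
  frame <- if (length(frame_line))
    sub(".*frame=([A-Za-z_]+).*", "\\1", frame_line[1L]) else "ULF_to_GGF"
  df <- utils::read.csv(file, comment.char = "#")
  orientation_series(df$t, as.matrix(df[, c("qx", "qy", "qz", "qw")]),
                     frame = frame)
}
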