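#' Cubic-spline resampling onto a uniform grid
#'
#' Resamples one or more uniformly (or non-uniformly) sampled signals onto a
#' uniform grid at `target_rate` spanning the original time range, using
#' cubic-spline interpolation.
#'
#' @param time numeric vector of sample times, strictly increasing, length
#'   >= 4.
#' @param values numeric vector or n x p matrix of signal values.
#' @param target_rate output sampling rate, samples/s.
#' @return List with elements `time` and `values` (matrix if the input was).
#' @export
resample_series <- function(time, values, target_rate) {
  if (length(time) < 4L) stop("need at least 4 samples to resample")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  if (target_rate <= 0) stop("'target_rate' must be positive")
  new_t <- seq(time[1L], time[length(time)], by = 1 / target_rate)
  vm <- as.matrix(values)
  out <- apply(vm, 2L, function(col)
    stats::splinefun(time, col, method = "fmm")(new_t))
  if (is.null(dim(values))) out <- drop(out)
  list(time = new_t, values = out)
}

#' Resample a MIMU trace
#'
#' Applies [resample_series()] to every sensor stream of a trace.
#'
#' @param trace a [mimu_trace()].
#' @param target_rate output rate, samples/s (e.g. 200).
#' @return A resampled [mimu_trace()].
#' @export
resample_trace <- function(trace, target_rate) {
  stopifnot(inherits(trace, "mimu_trace"))
  g <- resample_series(trace$time, trace$gyro, target_rate)
  a <- resample_series(trace$time, trace$accel, target_rate)
  m <- resample_series(trace$time, trace$mag, target_rate)
  mimu_trace(g$time, g$values, a$values, m$values,
             sample_rate = target_rate, meta = trace$meta)
}

#' Zero-lag low-pass Butterworth filtering
#'
#' Second-order (by default) low-pass Butterworth filter applied forward and
#' backward so the net phase lag is zero.
#'
#' @param x numeric vector or n x p matrix of signal values.
#' @param cutoff cutoff frequency, Hz; must lie in (0, Nyquist).
#' @param fs sampling rate, samples/s.
#' @param order filter order of the single pass (default 2).
#' @return Filtered signal with the shape of `x`.
#' @export
lowpass_zero_lag <- function(x, cutoff, fs, order = 2L) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("'cutoff' must lie strictly between 0 and the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  xm <- as.matrix(x)
  n <- nrow(xm)
  # odd reflection padding at both ends suppresses the start-up transient of
  # the forward-backward pass
  pad <- min(n - 1L, max(64L, ceiling(8 * fs / cutoff)))
  out <- apply(xm, 2L, function(col) {
    ext <- c(2 * col[1L] - col[(pad + 1L):2L],
             col,
             2 * col[n] - col[(n - 1L):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1L):(pad + n)]
  })
  if (is.null(dim(x))) out <- drop(out)
  out
}

#' Residual-analysis selection of the low-pass cutoff frequency
#'
#' Winter's residual analysis: for each candidate cutoff the RMS residual
#' between the raw and the zero-lag-filtered signal is computed; a straight
#' line is fitted to the noise-dominated upper half of the residual curve,
#' and the selected cutoff is the lowest candidate whose residual does not
#' exceed that line's intercept (the estimated noise floor at 0 Hz). A flat
#' residual curve (noise-free input) returns the upper bound of the range
#' with a warning.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate, samples/s.
#' @param candidates candidate cutoffs, Hz (default 0.5 to 15 Hz in 0.25 Hz
#'   steps, truncated below Nyquist).
#' @param order single-pass Butterworth order (default 2).
#' @return Selected cutoff in Hz, with the residual curve attached as
#'   attributes `candidates` and `residuals`.
#' @export
residual_analysis_cutoff <- function(x, fs,
                                     candidates = seq(0.5, 15, by = 0.25),
                                     order = 2L) {
  candidates <- candidates[candidates < fs / 2]
  if (length(candidates) < 4L) stop("need at least 4 candidate cutoffs")
  res <- vapply(candidates, function(fc)
    sqrt(mean((x - lowpass_zero_lag(x, fc, fs, order))^2)), numeric(1))
  out_attr <- function(fc) structure(fc, candidates = candidates,
                                     residuals = res)
  if (max(res) < 1e-10 * max(1, max(abs(x)))) {
    warning("flat residual curve (noise-free signal); returning upper bound")
    return(out_attr(max(candidates)))
  }
  upper <- candidates >= stats::median(candidates)
  fit <- stats::lm.fit(cbind(1, candidates[upper]), res[upper])
  noise_floor <- fit$coefficients[1L]
  ok <- which(res <= noise_floor)
  if (!length(ok)) {
    warning("residual curve never meets the noise-floor intercept; ",
            "returning upper bound")
    return(out_attr(max(candidates)))
  }
  out_attr(candidates[min(ok)])
}

#' Static gyro bias estimation
#'
#' Per-axis mean of the gyroscope measurements over a stationary
#' acquisition; the caller subtracts the result from the whole angular
#' velocity time series. The acquisition is verified to be static by
#' requiring the per-axis gyro standard deviation to stay below three times
#' the nominal noise level.
#'
#' @param static_trace a [mimu_trace()] acquired with the unit at rest.
#' @param nominal_noise_sd nominal gyro white-noise SD, deg/s (default 2.5).
#' @return 3-vector bias estimate in deg/s.
#' @export
estimate_gyro_bias <- function(static_trace, nominal_noise_sd = 2.5) {
  stopifnot(inherits(static_trace, "mimu_trace"))
  sds <- apply(static_trace$gyro, 2L, stats::sd)
  if (any(sds > 3 * nominal_noise_sd))
    stop("gyro variability exceeds 3x the nominal noise level: ",
         "the acquisition does not look static (motion contamination?)")
  colMeans(static_trace$gyro)
}

#' Subtract a gyro bias from a trace
#'
#' @param trace a [mimu_trace()].
#' @param bias 3-vector in deg/s, e.g. from [estimate_gyro_bias()].
#' @return The corrected trace.
#' @export
correct_gyro_bias <- function(trace, bias) {
  stopifnot(inherits(trace, "mimu_trace"), length(bias) == 3L)
  trace$gyro <- sweep(trace$gyro, 2L, bias, `-`)
  trace
}

#' Accelerometer static calibration check
#'
#' Takes three static acquisitions in which each sensor axis in turn is
#' aligned with the gravitational field vector (pointing down). The
#' per-axis signal means are compared with their expected values (-1 g on
#' the aligned axis, 0 elsewhere) and the maximal absolute deviation is
#' returned in m/s^2, with a pass flag against the tolerance.
#'
#' @param traces list of three [mimu_trace()] objects.
#' @param axes integer vector giving, for each trace, which axis (1..3) was
#'   aligned with gravity (default 1:3).
#' @param tolerance pass/fail tolerance, m/s^2 (default 0.02).
#' @param g gravitational acceleration, m/s^2.
#' @return Maximal deviation in m/s^2 with attribute `pass`.
#' @export
accel_static_check <- function(traces, axes = 1:3, tolerance = 0.02,
                               g = 9.81) {
  if (!is.list(traces) || length(traces) != 3L)
    stop("three static traces (one per axis) are required")
  devs <- numeric(0)
  for (k in seq_along(traces)) {
    stopifnot(inherits(traces[[k]], "mimu_trace"))
    mu <- colMeans(traces[[k]]$accel) * g
    expected <- c(0, 0, 0); expected[axes[k]] <- -g
    devs <- c(devs, abs(mu - expected))
  }
  structure(max(devs), pass = max(devs) <= tolerance)
}

#' Axis-aligned magnetometer ellipsoid calibration
#'
#' Least-squares estimation of the per-axis biases (hard iron) and
#' sensitivities of a tri-axial magnetometer from an acquisition in which
#' the unit is freely rotated about its three axes. The distorted samples
#' lie on an axis-aligned ellipsoid; its centre gives the bias and the
#' ratios of its semi-axes to the reference field magnitude give the
#' per-axis sensitivities. Applying the returned correction,
#' `(m - bias) / sensitivity`, maps the samples back onto a sphere of the
#' reference radius.
#'
#' @param x a [mimu_trace()] (its magnetometer stream is used) or an n x 3
#'   matrix of field samples in uT.
#' @param reference_magnitude known magnitude of the undistorted field, uT;
#'   if `NULL`, sensitivities are normalized to a unit geometric mean.
#' @param condition_limit reject acquisitions whose design matrix condition
#'   number exceeds this bound (insufficient rotation coverage).
#' @return List with `bias` (uT), `sensitivity` (dimensionless) and
#'   `radius` (fitted sphere radius after correction, uT).
#' @export
calibrate_magnetometer <- function(x, reference_magnitude = NULL,
                                   condition_limit = 1e8) {
  m <- if (inherits(x, "mimu_trace")) x$mag else as.matrix(x)
  if (ncol(m) != 3L || nrow(m) < 9L)
    stop("need an n x 3 matrix of at least 9 field samples")
  D <- cbind(m^2, m)
  if (kappa(D) > condition_limit)
    stop("insufficient rotation: the acquisition does not cover enough ",
         "orientations for an ellipsoid fit")
  beta <- stats::lm.fit(D, rep(1, nrow(m)))$coefficients
  A <- beta[1:3]; b <- beta[4:6]
  if (any(A <= 0))
    stop("degenerate ellipsoid fit (non-positive quadratic coefficients)")
  centre <- -b / (2 * A)
  gain <- 1 + sum(A * centre^2)
  semi_axes <- sqrt(gain / A)
  ref <- if (is.null(reference_magnitude)) prod(semi_axes)^(1 / 3)
  else reference_magnitude
  list(bias = unname(centre), sensitivity = unname(semi_axes / ref),
       radius = ref)
}

#' Apply a magnetometer calibration to a trace
#'
#' @param trace a [mimu_trace()].
#' @param calibration result of [calibrate_magnetometer()].
#' @return Trace with corrected magnetometer stream.
#' @export
apply_mag_calibration <- function(trace, calibration) {
  stopifnot(inherits(trace, "mimu_trace"))
  trace$mag <- sweep(sweep(trace$mag, 2L, calibration$bias, `-`),
                     2L, calibration$sensitivity, `/`)
  trace
}
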