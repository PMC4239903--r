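#' Fit an orientation estimate to a MIMU trace
#'
#' Front-end to the three estimators: numerical integration of the
#' quaternion kinematic equation (`"int"`), the ten-state extended Kalman
#' filter with vector-selection gating (`"sf"`), and the gradient-descent
#' complementary filter (`"cf"`). Returns a fitted-model object with the
#' usual accessor methods; if a reference orientation is supplied, accuracy
#' summaries and residual error series are available through `summary()`
#' and `residuals()`.
#'
#' @param trace a [mimu_trace()].
#' @param method one of `"int"`, `"sf"`, `"cf"`.
#' @param params method parameters: an [sf_params()] for `"sf"`, a
#'   [cf_params()] for `"cf"`; defaults are the manual-routine EKF preset
#'   and beta = 0.1 rad/s.
#' @param gyro_bias optional static gyro bias (deg/s) subtracted before
#'   estimation, e.g. from [estimate_gyro_bias()].
#' @param reference optional ground-truth [orientation_series()] for
#'   accuracy assessment.
#' @param q0 initial quaternion (default identity: the global frame is
#'   defined by the initial static posture).
#' @param ... passed to the underlying estimator.
#' @return Object of class `orient_fit`.
#' @examples
#' truth <- make_manual_routine(seed = 1)
#' trace <- synthesize_trace(truth, sensor_model(), seed = 1)
#' fit <- fit_orientation(trace, method = "cf", reference = truth$orientation)
#' summary(fit)
#' @export
fit_orientation <- function(trace, method = c("int", "sf", "cf"),
                            params = NULL, gyro_bias = NULL,
                            reference = NULL, q0 = quat_identity(), ...) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "mimu_trace"))
  if (!is.null(gyro_bias)) trace <- correct_gyro_bias(trace, gyro_bias)
  orientation <- switch(method,
    int = int_estimator(trace, q0 = q0),
    sf = {
      if (is.null(params)) params <- sf_params("manual")
      sf_estimator(trace, params, q0 = q0, ...)
    },
    cf = {
      if (is.null(params)) params <- cf_params()
      cf_estimator(trace, params, q0 = q0)
    })
  structure(list(orientation = orientation, method = method,
                 params = params, trace = trace, reference = reference,
                 gyro_bias = gyro_bias, call = match.call()),
            class = "orient_fit")
}

#' @export
print.orient_fit <- function(x, ...) {
  cat(sprintf("Orientation fit (%s), %d samples at %g samples/s\n",
              toupper(x$method), length(x$orientation$time),
              x$trace$sample_rate))
  if (!is.null(x$params)) {
    p <- unclass(x$params)
    p <- p[vapply(p, is.numeric, logical(1))]
    cat("  parameters:", paste(sprintf("%s=%g", names(p), unlist(p)),
                               collapse = ", "), "\n")
  }
  if (!is.null(x$reference)) {
    s <- rms_summary(residuals(x))
    cat(sprintf("  vs reference: RMS_head %.2f deg, RMS_att %.2f deg\n",
                s[["rms_head"]], s[["rms_att"]]))
  }
  invisible(x)
}

#' @export
coef.orient_fit <- function(object, ...) {
  if (is.null(object$params)) return(numeric(0))
  p <- unclass(object$params)
  unlist(p[vapply(p, is.numeric, logical(1))])
}

#' @export
residuals.orient_fit <- function(object, reference = object$reference, ...) {
  if (is.null(reference))
    stop("no reference orientation available; supply 'reference'")
  error_series(reference, object$orientation)
}

#' @export
summary.orient_fit <- function(object, exclude_prologue = 0, ...) {
  ans <- list(method = object$method, n = length(object$orientation$time),
              duration = diff(range(object$orientation$time)),
              euler_range = apply(orientation_euler(object$orientation), 2L,
                                  function(a) diff(range(a))))
  if (!is.null(object$reference))
    ans$accuracy <- rms_summary(residuals(object),
                                exclude_prologue = exclude_prologue)
  class(ans) <- "summary.orient_fit"
  ans
}

#' @export
print.summary.orient_fit <- function(x, ...) {
  cat(sprintf("Orientation fit (%s): %d samples over %.1f s\n",
              toupper(x$method), x$n, x$duration))
  cat(sprintf("  excursion: yaw %.1f deg, pitch %.1f deg, roll %.1f deg\n",
              x$euler_range[1L], x$euler_range[2L], x$euler_range[3L]))
  if (!is.null(x$accuracy))
    cat(sprintf(
      "  accuracy vs reference: RMS_head %.2f deg, RMS_att %.2f deg, RMS %.2f deg\n",
      x$accuracy[["rms_head"]], x$accuracy[["rms_att"]],
      x$accuracy[["rms_total"]]))
  invisible(x)
}

#' @export
plot.orient_fit <- function(x, which = c("euler", "error"), ...) {
  which <- match.arg(which)
  if (which == "euler") {
    ang <- orientation_euler(x$orientation)
    graphics::matplot(x$orientation$time, ang, type = "l", lty = 1,
                      col = c("firebrick", "steelblue", "darkgreen"),
                      xlab = "time [s]", ylab = "angle [deg]",
                      main = sprintf("%s estimate", toupper(x$method)), ...)
    graphics::legend("topright", c("yaw", "pitch", "roll"), lty = 1,
                     col = c("firebrick", "steelblue", "darkgreen"), bty = "n")
  } else {
    err <- residuals(x)
    graphics::matplot(err$time, cbind(err$heading_err, err$attitude_err),
                      type = "l", lty = 1,
                      col = c("firebrick", "steelblue"),
                      xlab = "time [s]", ylab = "error [deg]", ...)
    graphics::legend("topleft", c("heading", "attitude"), lty = 1,
                     col = c("firebrick", "steelblue"), bty = "n")
  }
  invisible(x)
}

#' @export
predict.orient_fit <- function(object, times = NULL, ...) {
  os <- object$orientation
  if (is.null(times)) return(os)
  if (any(times < os$time[1L] | times > os$time[length(os$time)]))
    stop("'times' outside the fitted range")
  qi <- vapply(seq_len(4L), function(j)
    stats::splinefun(os$time, os$quat[, j], method = "fmm")(times),
    numeric(length(times)))
  qi <- matrix(qi, ncol = 4L)
  orientation_series(times, qi / sqrt(rowSums(qi^2)), frame = os$frame)
}
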