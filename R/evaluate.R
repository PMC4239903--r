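# rowwise Hamilton product of two n x 4 quaternion matrices, renormalized
qmul_rows2 <- function(A, B) {
  ax <- A[, 1L]; ay <- A[, 2L]; az <- A[, 3L]; aw <- A[, 4L]
  bx <- B[, 1L]; by <- B[, 2L]; bz <- B[, 3L]; bw <- B[, 4L]
  x <- aw * bx + bw * ax + ay * bz - az * by
  y <- aw * by + bw * ay + az * bx - ax * bz
  z <- aw * bz + bw * az + ax * by - ay * bx
  w <- aw * bw - ax * bx - ay * by - az * bz
  out <- cbind(x, y, z, w)
  out / sqrt(rowSums(out^2))
}

#' Orientation error series with heading/attitude decomposition
#'
#' Computes the per-sample error quaternion between a reference and an
#' estimated orientation series, the total orientation error angle
#' `delta_theta = 2*acos(|delta_q4|)`, and its decoupling into a heading
#' error (the twist of the error rotation about the global vertical axis)
#' and an attitude error (the angle of the residual swing rotation) via the
#' swing-twist factorization. The twist angle about the vertical is
#' invariant to expressing the error rotation in the global or in the
#' reference body frame, so the decomposition is frame-consistent.
#'
#' @param reference,estimate [orientation_series()] objects with identical
#'   timestamps and the same frame convention (resample first if needed).
#' @return Object of class `error_series` with fields `time`, `delta_q`
#'   (n x 4), `delta_theta`, `heading_err`, `attitude_err` (all degrees).
#' @export
error_series <- function(reference, estimate) {
  stopifnot(inherits(reference, "orientation_series"),
            inherits(estimate, "orientation_series"))
  if (reference$frame != estimate$frame)
    stop("frame conventions differ; convert with invert_frame() first")
  if (length(reference$time) != length(estimate$time) ||
      max(abs(reference$time - estimate$time)) > 1e-9)
    stop("timestamps differ; resample one series first")
  ref <- if (reference$frame == "ULF_to_GGF") reference else
    invert_frame(reference)
  est <- if (estimate$frame == "ULF_to_GGF") estimate else
    invert_frame(estimate)

  conj_ref <- ref$quat
  conj_ref[, 1:3] <- -conj_ref[, 1:3]
  dq <- qmul_rows2(est$quat, conj_ref)   # error rotation, global frame

  delta_theta <- 2 * acos(pmin(1, abs(dq[, 4L]))) * 180 / pi
  tz <- dq[, 3L]; w <- dq[, 4L]
  tn <- sqrt(tz^2 + w^2)
  raw <- 2 * atan2(tz, w)
  raw <- raw - 2 * pi * round(raw / (2 * pi))
  heading <- abs(raw) * 180 / pi
  heading[tn < 1e-12] <- 0          # degenerate: pure 180-degree swing
  attitude <- 2 * acos(pmin(1, tn)) * 180 / pi

  structure(list(time = ref$time, delta_q = dq, delta_theta = delta_theta,
                 heading_err = heading, attitude_err = attitude),
            class = "error_series")
}

#' @export
print.error_series <- function(x, ...) {
  cat(sprintf(
    "<error_series> %d samples; RMS total %.2f deg (heading %.2f, attitude %.2f)\n",
    length(x$time), sqrt(mean(x$delta_theta^2)),
    sqrt(mean(x$heading_err^2)), sqrt(mean(x$attitude_err^2))))
  invisible(x)
}

#' RMS accuracy summary of an error series
#'
#' Root-mean-square values of the total, heading and attitude error angles,
#' optionally discarding an initial prologue.
#'
#' @param err an [error_series()].
#' @param exclude_prologue seconds to drop from the start (default 0).
#' @return Named numeric vector `c(rms_head, rms_att, rms_total)` in degrees.
#' @export
rms_summary <- function(err, exclude_prologue = 0) {
  stopifnot(inherits(err, "error_series"))
  keep <- err$time >= err$time[1L] + exclude_prologue
  if (!any(keep)) stop("'exclude_prologue' removes every sample")
  c(rms_head = sqrt(mean(err$heading_err[keep]^2)),
    rms_att = sqrt(mean(err$attitude_err[keep]^2)),
    rms_total = sqrt(mean(err$delta_theta[keep]^2)))
}

#' Pointwise mean and SD error curves over repeated trials
#'
#' @param trials list of equal-length [error_series()] objects.
#' @return List with `time` and matrices `mean`/`sd` (columns `heading`,
#'   `attitude`, `total`), class `error_curves`.
#' @export
error_vs_time_curves <- function(trials) {
  if (!length(trials)) stop("no trials supplied")
  lens <- vapply(trials, function(e) length(e$time), integer(1))
  if (length(unique(lens)) != 1L) stop("trials differ in length")
  stack <- function(field) do.call(cbind, lapply(trials, `[[`, field))
  sd0 <- function(m) if (ncol(m) < 2L) rep(0, nrow(m)) else apply(m, 1L, stats::sd)
  h <- stack("heading_err"); a <- stack("attitude_err"); d <- stack("delta_theta")
  structure(list(
    time = trials[[1L]]$time,
    mean = cbind(heading = rowMeans(h), attitude = rowMeans(a),
                 total = rowMeans(d)),
    sd = cbind(heading = sd0(h), attitude = sd0(a), total = sd0(d))),
    class = "error_curves")
}

#' @export
plot.error_curves <- function(x, component = c("heading", "attitude", "total"),
                              col = "steelblue", add = FALSE, ...) {
  component <- match.arg(component)
  m <- x$mean[, component]; s <- x$sd[, component]
  if (!add) {
    graphics::plot(x$time, m, type = "n", ylim = range(0, m + s),
                   xlab = "time [s]",
                   ylab = sprintf("%s error [deg]", component), ...)
  }
  graphics::polygon(c(x$time, rev(x$time)), c(m + s, rev(pmax(0, m - s))),
                    col = grDevices::adjustcolor(col, 0.25), border = NA)
  graphics::lines(x$time, m, col = col, lwd = 2)
  invisible(x)
}

default_scenario_model <- function(scenario, sample_rate = 128) {
  sensor_model(gyro_bias = c(0.3, -0.2, 0.4),
               gyro_bias_walk_sd = if (scenario == "locomotion") 0.01 else 0,
               sample_rate = sample_rate)
}

#' Synthetic accuracy benchmark of the orientation estimators
#'
#' Runs the full assessment pipeline on `n_trials` seeded synthetic trials
#' of one motor scenario: generate the ground truth, synthesize the MIMU
#' measurements, estimate (and optionally subtract) the static gyro bias
#' from a companion table acquisition, run the requested estimators, and
#' summarize per-trial heading/attitude RMS errors. Manual-routine trials
#' include a transient 200 uT magnet event by default, emulating a reach
#' towards a magnet on the table.
#'
#' @param scenario `"manual"` or `"locomotion"`.
#' @param methods subset of `c("int", "sf", "cf")`.
#' @param n_trials number of trials (default 6).
#' @param seeds integer seeds, one per trial (default `1:n_trials`).
#' @param model a [sensor_model()]; default uses the scenario noise levels
#'   with a constant gyro bias of `c(0.3, -0.2, 0.4)` deg/s.
#' @param bias_correction subtract the estimated static bias before
#'   estimation (default TRUE).
#' @param static_duration length of the bias-calibration acquisition, s
#'   (default 180 s, long enough that the residual bias standard error is
#'   below 0.02 deg/s per axis).
#' @param magnet_event add a 200 uT, 5 s magnet event (default TRUE for the
#'   manual routine, FALSE otherwise).
#' @param beta complementary-filter gain, rad/s.
#' @param exclude_prologue seconds excluded from the RMS (default 0).
#' @param keep_curves retain per-trial error series for error-vs-time curves.
#' @return Object of class `mimu_benchmark`: per-trial `table`, per-method
#'   `aggregate` (mean and SD of the RMS errors), per-method error `curves`,
#'   and the configuration.
#' @export
run_benchmark <- function(scenario = c("manual", "locomotion"),
                          methods = c("int", "sf", "cf"),
                          n_trials = 6L, seeds = NULL, model = NULL,
                          bias_correction = TRUE, static_duration = 180,
                          magnet_event = NULL, beta = 0.1,
                          exclude_prologue = 0, keep_curves = TRUE) {
  scenario <- match.arg(scenario)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(seeds)) seeds <- seq_len(n_trials)
  n_trials <- length(seeds)
  if (is.null(magnet_event)) magnet_event <- scenario == "manual"
  if (is.null(model)) model <- default_scenario_model(scenario)

  rows <- list()
  errs <- stats::setNames(vector("list", length(methods)), methods)
  for (i in seq_along(seeds)) {
    seed <- seeds[i]
    truth <- if (scenario == "manual")
      make_manual_routine(seed = seed, sample_rate = model$sample_rate)
    else make_locomotion(seed = seed, sample_rate = model$sample_rate)
    if (magnet_event)
      truth <- add_magnet_event(truth, start = 35, duration = 5, peak = 200)
    trace <- synthesize_trace(truth, model, seed = seed + 5000L)
    if (bias_correction) {
      static <- make_static_trace(static_duration, model, seed = seed + 9000L)
      trace <- correct_gyro_bias(
        trace, estimate_gyro_bias(static, model$gyro_noise_sd))
    }
    for (m in methods) {
      est <- switch(m,
        int = int_estimator(trace),
        sf = sf_estimator(trace, sf_params(
          if (scenario == "manual") "manual" else "locomotion")),
        cf = cf_estimator(trace, cf_params(beta = beta)))
      err <- error_series(truth$orientation, est)
      s <- rms_summary(err, exclude_prologue)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = i, seed = seed, method = m,
        rms_head = s[["rms_head"]], rms_att = s[["rms_att"]],
        rms_total = s[["rms_total"]])
      if (keep_curves) errs[[m]] <- c(errs[[m]], list(err))
    }
  }
  tab <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(tab, tab$method), function(d)
    data.frame(method = d$method[1L], n = nrow(d),
               mean_rms_head = mean(d$rms_head), sd_rms_head = stats::sd(d$rms_head),
               mean_rms_att = mean(d$rms_att), sd_rms_att = stats::sd(d$rms_att))))
  rownames(agg) <- NULL
  curves <- if (keep_curves)
    lapply(errs[!vapply(errs, is.null, logical(1))], error_vs_time_curves)
  else NULL
  structure(list(table = tab, aggregate = agg, curves = curves,
                 trial_errors = if (keep_curves) errs else NULL,
                 config = list(scenario = scenario, methods = methods,
                               seeds = seeds, bias_correction = bias_correction,
                               magnet_event = magnet_event, beta = beta,
                               static_duration = static_duration,
                               model = model)),
            class = "mimu_benchmark")
}

#' @export
print.mimu_benchmark <- function(x, ...) {
  cat(sprintf("<mimu_benchmark> %s scenario, %d trials (seeds %s)\n",
              x$config$scenario, length(x$config$seeds),
              paste(x$config$seeds, collapse = ", ")))
  cat(sprintf("  bias correction: %s; magnet event: %s\n",
              x$config$bias_correction, x$config$magnet_event))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-3s  RMS_head %5.2f +- %.2f deg   RMS_att %5.2f +- %.2f deg\n",
                toupper(agg$method[i]), agg$mean_rms_head[i], agg$sd_rms_head[i],
                agg$mean_rms_att[i], agg$sd_rms_att[i]))
  invisible(x)
}

#' @export
plot.mimu_benchmark <- function(x, component = c("heading", "attitude"), ...) {
  component <- match.arg(component)
  if (is.null(x$curves)) stop("benchmark was run with keep_curves = FALSE")
  cols <- c(int = "firebrick", sf = "steelblue", cf = "darkgreen")
  first <- TRUE
  ymax <- max(vapply(x$curves, function(cv)
    max(cv$mean[, component] + cv$sd[, component]), numeric(1)))
  for (m in names(x$curves)) {
    if (first) {
      graphics::plot(x$curves[[m]]$time, x$curves[[m]]$mean[, component],
                     type = "n", ylim = c(0, ymax), xlab = "time [s]",
                     ylab = sprintf("%s error [deg]", component),
                     main = sprintf("%s task", x$config$scenario), ...)
      first <- FALSE
    }
    plot(x$curves[[m]], component = component, col = cols[[m]], add = TRUE)
  }
  graphics::legend("topleft", legend = toupper(names(x$curves)),
                   col = cols[names(x$curves)], lwd = 2, bty = "n")
  invisible(x)
}
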