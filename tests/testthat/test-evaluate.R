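make_series <- function(tt, qfun) {
  orientation_series(tt, t(vapply(tt, qfun, numeric(4))))
}

test_that("error quaternion and its swing-twist decomposition behave on closed-form cases", {
  tt <- seq(0, 1, by = 0.1)
  ref <- make_series(tt, function(t) quat_from_euler(40 * t, 10 * t, -5 * t))
  # identical series: all errors identically zero
  e0 <- error_series(ref, ref)
  expect_equal(max(e0$delta_theta), 0, tolerance = 1e-6)
  expect_equal(rms_summary(e0), c(rms_head = 0, rms_att = 0, rms_total = 0),
               tolerance = 1e-6)
  # a pure 30-degree yaw error composed in the global frame
  yaw30 <- quat_from_axis_angle(c(0, 0, 1), 30 * pi / 180)
  est <- make_series(tt, function(t)
    quat_multiply(yaw30, quat_from_euler(40 * t, 10 * t, -5 * t)))
  e1 <- error_series(ref, est)
  expect_equal(unname(e1$heading_err), rep(30, length(tt)), tolerance = 1e-9)
  expect_equal(max(e1$attitude_err), 0, tolerance = 1e-9)
  expect_equal(unname(e1$delta_theta), rep(30, length(tt)), tolerance = 1e-9)
})

test_that("small orientation errors satisfy the Pythagorean decomposition", {
  set.seed(71)
  tt <- 0:19 / 10
  ref <- make_series(tt, function(t) quat_from_euler(25 * t, 5 * t, 3 * t))
  for (i in 1:10) {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- runif(1, 0.5, 5) * pi / 180
    derr <- quat_from_axis_angle(axis, ang)
    est <- orientation_series(tt, t(apply(ref$quat, 1, function(q)
      quat_multiply(derr, q))))
    e <- error_series(ref, est)
    expect_equal(e$delta_theta^2, e$heading_err^2 + e$attitude_err^2,
                 tolerance = 0.01)
  }
})

test_that("the decomposition recomposes the error quaternion and is symmetric", {
  set.seed(72)
  tt <- 0:9 / 10
  ref <- make_series(tt, function(t) quat_from_euler(120 * t, 30 * t, -20 * t))
  est <- make_series(tt, function(t)
    quat_from_euler(120 * t + 12, 30 * t - 6, -20 * t + 4))
  e <- error_series(ref, est)
  for (k in seq_along(tt)) {
    dq <- e$delta_q[k, ]
    twist <- quat_normalize(c(0, 0, dq[3], dq[4]))
    swing <- quat_multiply(dq, quat_conjugate(twist))
    expect_lt(quat_angle_deg(quat_multiply(swing, twist), dq), 1e-6)
    expect_equal(quat_angle(twist) * 180 / pi, e$heading_err[k],
                 tolerance = 1e-9)
    expect_equal(quat_angle(swing) * 180 / pi, e$attitude_err[k],
                 tolerance = 1e-9)
  }
  # swapping reference and estimate leaves the total error angle unchanged
  e_rev <- error_series(est, ref)
  expect_equal(e$delta_theta, e_rev$delta_theta, tolerance = 1e-9)
})

test_that("mismatched inputs are rejected", {
  tt <- 0:9 / 10
  a <- identity_series(tt)
  expect_error(error_series(a, identity_series(tt + 0.5)), "timestamps")
  expect_error(error_series(a, invert_frame(identity_series(tt))), "frame")
})

test_that("RMS summaries reduce to closed forms", {
  tt <- seq(0, 10, by = 1 / 64)
  # constant 3-degree yaw offset
  off3 <- quat_from_axis_angle(c(0, 0, 1), 3 * pi / 180)
  const3 <- orientation_series(tt, matrix(off3, length(tt), 4, byrow = TRUE))
  expect_equal(rms_summary(error_series(identity_series(tt), const3))[["rms_head"]],
               3, tolerance = 1e-9)
  # alternating +-4 degrees
  alt <- make_series(tt, function(t)
    quat_from_axis_angle(c(0, 0, 1), (-1)^(round(t * 64)) * 4 * pi / 180))
  expect_equal(rms_summary(error_series(identity_series(tt), alt))[["rms_head"]],
               4, tolerance = 1e-9)
  # linear drift 0 -> b gives RMS b/sqrt(3)
  b <- 12
  drift <- make_series(tt, function(t)
    quat_from_axis_angle(c(0, 0, 1), b * (t / 10) * pi / 180))
  expect_equal(rms_summary(error_series(identity_series(tt), drift))[["rms_head"]],
               b / sqrt(3), tolerance = 0.01 * b)
  # prologue exclusion drops the early samples
  s <- rms_summary(error_series(identity_series(tt), drift),
                   exclude_prologue = 5)
  expect_gt(s[["rms_head"]], b / sqrt(3))
})

test_that("mean and SD curves aggregate repeated trials", {
  tt <- 0:99 / 10
  mk <- function(scale) {
    est <- make_series(tt, function(t)
      quat_from_axis_angle(c(0, 0, 1), scale * t * pi / 180))
    error_series(identity_series(tt), est)
  }
  single <- error_vs_time_curves(list(mk(1)))
  expect_equal(max(single$sd), 0)
  twin <- error_vs_time_curves(list(mk(1), mk(1)))
  expect_equal(twin$mean[, "heading"], mk(1)$heading_err)
  expect_equal(max(twin$sd), 0)
  pair <- error_vs_time_curves(list(mk(1), mk(2)))
  expect_gt(max(pair$sd), 0)
  short <- error_series(identity_series(tt[1:50]),
                        identity_series(tt[1:50]))
  expect_error(error_vs_time_curves(list(mk(1), short)), "length")
})

test_that("the benchmark driver produces a reproducible bookkeeping table", {
  b1 <- run_benchmark("manual", methods = c("int", "cf"), seeds = 1:2,
                      keep_curves = FALSE)
  expect_equal(nrow(b1$table), 4L)
  expect_equal(sort(unique(b1$table$method)), c("cf", "int"))
  # aggregates are recomputable from the per-trial table
  for (m in c("cf", "int")) {
    rows <- b1$table[b1$table$method == m, ]
    agg <- b1$aggregate[b1$aggregate$method == m, ]
    expect_equal(agg$mean_rms_head, mean(rows$rms_head))
    expect_equal(agg$sd_rms_att, sd(rows$rms_att))
  }
  b2 <- run_benchmark("manual", methods = c("int", "cf"), seeds = 1:2,
                      keep_curves = FALSE)
  expect_identical(b1$table, b2$table)
  expect_error(run_benchmark("manual", methods = "kalman"), "arg")
})

test_that("the fitted-model interface exposes the standard accessors", {
  truth <- short_manual(seed = 3, duration = 25)
  tr <- synthesize_trace(truth, sensor_model(), seed = 3)
  fit <- fit_orientation(tr, method = "cf", reference = truth$orientation)
  expect_s3_class(fit, "orient_fit")
  expect_output(print(fit), "RMS_head")
  expect_equal(coef(fit)[["beta"]], 0.1)
  res <- residuals(fit)
  expect_s3_class(res, "error_series")
  s <- summary(fit)
  expect_s3_class(s, "summary.orient_fit")
  expect_true(s$accuracy[["rms_head"]] >= 0)
  pred <- predict(fit, times = c(1, 2.5, 10))
  expect_equal(length(pred$time), 3L)
  expect_equal(rowSums(pred$quat^2), rep(1, 3), tolerance = 1e-9)
  expect_error(predict(fit, times = 100), "range")
  grDevices::pdf(NULL)
  plot(fit); plot(fit, which = "error")
  grDevices::dev.off()
  # an INT fit carries no tunable parameters
  expect_length(coef(fit_orientation(tr, method = "int")), 0)
})

test_that("traces and orientation series survive a CSV round trip", {
  truth <- short_manual(seed = 2)
  tr <- synthesize_trace(truth, sensor_model(), seed = 2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_mimu_csv(tr, f1)
  back <- read_mimu_csv(f1)
  expect_equal(back$sample_rate, tr$sample_rate)
  expect_equal(back$gyro, tr$gyro, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$mag, tr$mag, tolerance = 1e-9, ignore_attr = TRUE)
  write_orientation_csv(truth$orientation, f2)
  oback <- read_orientation_csv(f2)
  expect_equal(oback$frame, "ULF_to_GGF")
  expect_equal(oback$quat, truth$orientation$quat, tolerance = 1e-9)
  unlink(c(f1, f2))
})
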