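test_that("manual-routine contracts hold across seeds", {
  for (seed in 1:10) {
    gt <- make_manual_routine(seed = seed)
    expect_gte(mean(gt$static_mask), 0.15)
    # leading 5 s static posture
    expect_true(all(gt$static_mask[gt$orientation$time < 5]))
    # static samples really are static
    expect_true(all(sqrt(rowSums(gt$omega[gt$static_mask, ]^2)) < 0.1))
    # roughly 120 degrees of rotation about each axis (within +-20%)
    totals <- gt$meta$axis_totals
    expect_true(all(totals >= 96 & totals <= 144))
  }
  expect_error(make_manual_routine(duration = 20), "too short")
})

test_that("locomotion contracts hold across seeds", {
  for (seed in 1:6) {
    gt <- make_locomotion(seed = seed)
    ang <- orientation_euler(gt$orientation)
    expect_gte(diff(range(ang[, "yaw"])), 240)
    expect_lte(diff(range(ang[, "yaw"])), 280)
    expect_lt(diff(range(ang[, "pitch"])), 10)
    expect_lt(diff(range(ang[, "roll"])), 10)
    # vertical-axis angular velocity dominates by roughly 3.6x
    moving <- gt$orientation$time > 10
    ratio <- mean(abs(gt$omega[moving, 3])) /
      mean(abs(gt$omega[moving, 1:2]))
    expect_gte(ratio, 3.0)
    expect_lte(ratio, 4.2)
    # no static phase after the prologue
    expect_true(!any(gt$static_mask[gt$orientation$time >= 5]))
  }
  expect_error(make_locomotion(duration = 6), "too short")
})

test_that("generators and synthesis are bit-reproducible for a fixed seed", {
  a <- make_manual_routine(seed = 3)
  b <- make_manual_routine(seed = 3)
  expect_identical(a, b)
  expect_identical(make_locomotion(seed = 4, duration = 30),
                   make_locomotion(seed = 4, duration = 30))
  m <- sensor_model()
  expect_identical(synthesize_trace(a, m, seed = 5),
                   synthesize_trace(b, m, seed = 5))
  expect_identical(make_static_trace(5, m, seed = 6),
                   make_static_trace(5, m, seed = 6))
})

test_that("ground-truth angular velocity matches the quaternion derivative", {
  for (gt in list(make_manual_routine(seed = 2),
                  make_locomotion(seed = 2, duration = 60))) {
    Q <- gt$orientation$quat
    n <- nrow(Q)
    dt <- 1 / gt$sample_rate
    fd <- matrix(0, n - 1L, 3L)
    for (k in seq_len(n - 1L)) {
      dq <- quat_multiply(quat_conjugate(Q[k, ]), Q[k + 1L, ])
      if (dq[4L] < 0) dq <- -dq
      fd[k, ] <- 2 * dq[1:3] / dt * 180 / pi
    }
    mid <- (gt$omega[-n, ] + gt$omega[-1L, ]) / 2
    expect_lt(sqrt(mean((fd - mid)^2)), 0.1)
  }
})

test_that("synthesized measurements obey the sensor physics in the static limit", {
  truth <- static_truth(10)
  tr <- synthesize_trace(truth, noiseless_model(), seed = 1)
  expect_equal(max(abs(tr$gyro)), 0)
  expect_equal(tr$accel, matrix(c(0, 0, -1), nrow(tr$accel), 3, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(tr$mag, matrix(REF_FIELD, nrow(tr$mag), 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("white-noise levels are reproduced in the sample moments", {
  model <- sensor_model()
  tr <- make_static_trace(60, model, seed = 8)   # n = 7680
  expect_true(all(abs(apply(tr$gyro, 2, sd) / model$gyro_noise_sd - 1) < 0.1))
  expect_true(all(abs(apply(tr$accel, 2, sd) / model$accel_noise_sd - 1) < 0.1))
  expect_true(all(abs(apply(tr$mag, 2, sd) / model$mag_noise_sd - 1) < 0.1))
})

test_that("a constant z gyro bias integrates into a linear heading drift", {
  truth <- static_truth(60)
  tr <- synthesize_trace(truth, noiseless_model(gyro_bias = c(0, 0, 0.5)),
                         seed = 1)
  yaw <- orientation_euler(int_estimator(tr))[, "yaw"]
  slope <- coef(lm(yaw ~ tr$time))[[2]]
  expect_equal(slope, 0.5, tolerance = 0.01)
})

test_that("static calibration acquisitions have the documented statistics", {
  model <- sensor_model(gyro_bias = c(0.3, -0.2, 0.4))
  tr <- make_static_trace(60, model, seed = 21)
  n <- length(tr$time)
  tol <- 3 * model$gyro_noise_sd / sqrt(n)
  expect_true(all(abs(colMeans(tr$gyro) - model$gyro_bias) < tol))
  expect_lt(abs(sqrt(sum(colMeans(tr$accel)^2)) - 1), 0.002)
})

test_that("magnet events add a separable bell-shaped disturbance", {
  truth <- static_truth(60)
  expect_identical(add_magnet_event(truth, 20, 5, peak = 0)$mag_disturbance,
                   truth$mag_disturbance)
  ev <- add_magnet_event(truth, 20, 5, peak = 200)
  mags <- sqrt(rowSums(ev$mag_disturbance^2))
  tt <- ev$orientation$time
  # peak reached at the window centre; untouched outside
  expect_gt(max(mags), 195)
  expect_equal(tt[which.max(mags)], 22.5, tolerance = 0.05)
  expect_true(all(mags[tt < 20 | tt > 25] == 0))
  # below 1% of the peak at the window edges
  edge <- which.min(abs(tt - 20))
  expect_lt(mags[edge] / max(mags), 0.01)
  # five-fold field magnification against an undisturbed static trace
  tr_ev <- synthesize_trace(ev, noiseless_model(), seed = 1)
  expect_gte(max(sqrt(rowSums(tr_ev$mag^2))), 5 * sqrt(sum(REF_FIELD^2)))
  # events must stay separable and inside the record
  expect_error(add_magnet_event(ev, 22, 5, peak = 50), "overlap")
  expect_error(add_magnet_event(truth, 58, 5, peak = 50), "outside")
})
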