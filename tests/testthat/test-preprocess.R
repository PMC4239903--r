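test_that("cubic-spline resampling is exact on cubics and invertible on band-limited signals", {
  t128 <- (0:(128 * 8 - 1)) / 128
  cubic <- 2 - 0.5 * t128 + 0.3 * t128^2 - 0.04 * t128^3
  out <- resample_series(t128, cubic, 200)
  truth <- 2 - 0.5 * out$time + 0.3 * out$time^2 - 0.04 * out$time^3
  interior <- out$time > 0.1 & out$time < max(t128) - 0.1
  expect_lt(max(abs(out$values - truth)[interior]), 1e-9)

  const <- resample_series(t128, rep(3.2, length(t128)), 200)
  expect_equal(unique(round(const$values, 12)), 3.2)

  # 128 -> 200 -> 128 round trip on a signal band-limited below 6 Hz
  sig <- sin(2 * pi * 1.3 * t128) + 0.7 * sin(2 * pi * 4.1 * t128 + 1) +
    0.4 * sin(2 * pi * 5.6 * t128 + 2)
  up <- resample_series(t128, sig, 200)
  back <- resample_series(up$time, up$values, 128)
  m <- min(length(back$values), length(sig))
  expect_lt(sqrt(mean((back$values[1:m] - sig[1:m])^2)), 1e-3 * sd(sig))

  expect_error(resample_series(c(0, 1, 1, 2), 1:4, 10), "increasing")
})

test_that("zero-lag Butterworth filtering has the expected magnitude response and no lag", {
  fs <- 200
  tt <- (0:(fs * 20 - 1)) / fs
  keep <- tt > 2 & tt < 18          # avoid filter transients
  pass <- sin(2 * pi * 1 * tt)
  stop_ <- sin(2 * pi * 50 * tt)
  fp <- lowpass_zero_lag(pass, 6, fs)
  fsg <- lowpass_zero_lag(stop_, 6, fs)
  expect_equal(sd(fp[keep]) / sd(pass[keep]), 1, tolerance = 0.01)
  expect_lt(sd(fsg[keep]) / sd(stop_[keep]), 0.05)
  expect_equal(lowpass_zero_lag(rep(2, 500), 6, fs), rep(2, 500),
               tolerance = 1e-9)
  # zero phase: cross-correlation with the clean sinusoid peaks at lag 0
  cc <- ccf(fp[keep], pass[keep], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(lowpass_zero_lag(pass, 120, fs), "Nyquist")
})

test_that("residual analysis finds a cutoff between signal and noise bands", {
  fs <- 200
  tt <- (0:(fs * 20 - 1)) / fs
  set.seed(31)
  # pure white noise: the residual curve is linear almost everywhere and the
  # chosen cutoff collapses to the bottom of the candidate range
  expect_lt(residual_analysis_cutoff(rnorm(length(tt)), fs)[1], 2)
  # band-limited signal + noise at 20 dB SNR: cutoff within a sensible band
  sig <- sin(2 * pi * 1.2 * tt) + 0.6 * sin(2 * pi * 2.7 * tt)
  cuts <- vapply(1:5, function(s) {
    set.seed(s)
    residual_analysis_cutoff(sig + rnorm(length(tt), sd = sqrt(mean(sig^2)) / 10),
                             fs)[1]
  }, numeric(1))
  expect_true(all(cuts >= 2 & cuts <= 8))
  expect_lt(sd(cuts), 0.5)   # stable across realizations
  # a noise-free (flat-residual) input falls back to the upper bound
  expect_warning(res <- residual_analysis_cutoff(rep(1.5, length(tt)), fs),
                 "flat")
  expect_equal(res[1], 15)
})

test_that("static gyro bias estimation is consistent and guards against motion", {
  model <- sensor_model(gyro_bias = c(0.3, -0.2, 0.5))
  tr <- make_static_trace(60, model, seed = 33)
  est <- estimate_gyro_bias(tr)
  tol <- 3 * model$gyro_noise_sd / sqrt(length(tr$time))
  expect_true(all(abs(est - model$gyro_bias) < tol))
  # error shrinks roughly as 1/sqrt(n): a 4x longer acquisition is closer on average
  errs <- sapply(1:6, function(s) {
    short <- estimate_gyro_bias(make_static_trace(15, model, seed = 100 + s))
    long <- estimate_gyro_bias(make_static_trace(240, model, seed = 200 + s))
    c(mean(abs(short - model$gyro_bias)), mean(abs(long - model$gyro_bias)))
  })
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
  # the guideline minimum: 5 s at 100 samples/s still yields a finite estimate
  m100 <- sensor_model(sample_rate = 100)
  expect_true(all(is.finite(estimate_gyro_bias(make_static_trace(5, m100,
                                                                 seed = 34)))))
  # a moving acquisition must be rejected
  moving <- synthesize_trace(make_locomotion(seed = 1, duration = 30), model,
                             seed = 35)
  expect_error(estimate_gyro_bias(moving), "static")
})

test_that("accelerometer static check flags calibration errors at the 0.02 m/s2 level", {
  model <- sensor_model()
  traces <- list(
    make_static_trace(60, model, seed = 41,
                      orientation = quat_from_axis_angle(c(0, 1, 0), -pi / 2)),
    make_static_trace(60, model, seed = 42,
                      orientation = quat_from_axis_angle(c(1, 0, 0), pi / 2)),
    make_static_trace(60, model, seed = 43))
  dev <- accel_static_check(traces)
  expect_lt(dev, 3 * 0.01 * 9.81 / sqrt(length(traces[[1]]$time)))
  expect_true(attr(dev, "pass"))
  # a 2% scale error on the x axis shows up as ~0.196 m/s^2
  bad <- traces
  bad[[1]]$accel[, 1] <- 1.02 * bad[[1]]$accel[, 1]
  dev2 <- accel_static_check(bad)
  expect_equal(as.numeric(dev2), 0.02 * 9.81, tolerance = 0.02)
  expect_false(attr(dev2, "pass"))
  expect_error(accel_static_check(traces[1:2]), "three")
})

test_that("magnetometer ellipsoid calibration recovers bias and sensitivities", {
  set.seed(51)
  n <- 500
  Q <- matrix(rnorm(4 * n), ncol = 4)
  Q <- Q / sqrt(rowSums(Q^2))
  body <- t(apply(Q, 1, function(q) quat_rotate(quat_conjugate(q), REF_FIELD)))
  sens <- c(1.05, 0.95, 1.02); iron <- c(10, -5, 8)
  distorted <- sweep(body, 2, sens, `*`) +
    matrix(iron, n, 3, byrow = TRUE)
  cal <- calibrate_magnetometer(distorted, reference_magnitude = 40)
  expect_equal(cal$bias, iron, tolerance = 1e-6)
  expect_equal(cal$sensitivity, sens, tolerance = 1e-6)
  # identity distortion: bias ~ 0, sensitivities ~ 1
  cal0 <- calibrate_magnetometer(body, reference_magnitude = 40)
  expect_lt(max(abs(cal0$bias)), 1e-6)
  expect_equal(cal0$sensitivity, c(1, 1, 1), tolerance = 1e-6)
  # with 3 uT noise and 5000 samples the bias is recovered within 0.5 uT
  for (s in 1:10) {
    set.seed(s)
    n2 <- 5000
    Q2 <- matrix(rnorm(4 * n2), ncol = 4)
    Q2 <- Q2 / sqrt(rowSums(Q2^2))
    b2 <- t(apply(Q2, 1, function(q) quat_rotate(quat_conjugate(q), REF_FIELD)))
    noisy <- sweep(b2, 2, sens, `*`) + matrix(iron, n2, 3, byrow = TRUE) +
      matrix(rnorm(3 * n2, sd = 3), n2, 3)
    expect_lt(max(abs(calibrate_magnetometer(noisy, 40)$bias - iron)), 0.5)
  }
})

test_that("degenerate rotation coverage is rejected and the round trip respheres the samples", {
  # yaw-only rotations leave the vertical axis unexplored
  yaw <- seq(0, 2 * pi, length.out = 300)
  ring <- t(vapply(yaw, function(a)
    quat_rotate(quat_conjugate(quat_from_axis_angle(c(0, 0, 1), a)), REF_FIELD),
    numeric(3)))
  expect_error(calibrate_magnetometer(ring, 40), "insufficient rotation")

  set.seed(52)
  n <- 2000
  Q <- matrix(rnorm(4 * n), ncol = 4); Q <- Q / sqrt(rowSums(Q^2))
  body <- t(apply(Q, 1, function(q) quat_rotate(quat_conjugate(q), REF_FIELD)))
  distorted <- sweep(body, 2, c(1.1, 0.9, 1.05), `*`) +
    matrix(c(15, -10, 5), n, 3, byrow = TRUE) + matrix(rnorm(3 * n), n, 3)
  cal <- calibrate_magnetometer(distorted, 40)
  corrected <- sweep(sweep(distorted, 2, cal$bias, `-`), 2, cal$sensitivity, `/`)
  expect_gt(sd(sqrt(rowSums(distorted^2))) / sd(sqrt(rowSums(corrected^2))), 5)
})
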