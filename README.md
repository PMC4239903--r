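# mimufusion

Quaternion-based 3-D orientation estimation for body-worn magnetic and
inertial measurement units (MIMUs), with tools to assess estimator accuracy
in human-movement scenarios.

A MIMU combines a tri-axial gyroscope, accelerometer and magnetometer. Its
orientation `q̄(t)` (a unit quaternion, scalar last, mapping the sensor
frame ULF into a gravity-aligned global frame GGF) can be obtained by
integrating the kinematic differential equation

    dq̄/dt = ½ Ω(ω) q̄,        Ω(ω) = [ −[ω×]   ω ]
                                      [ −ωᵀ     0 ]

driven by the gyroscope rate ω. Gyroscope bias and noise make this estimate
drift, so aiding sensors are fused in: the accelerometer observes the
gravity direction (attitude — roll and pitch) whenever the unit is
quasi-static, and the magnetometer observes the horizontal field direction
(heading — yaw). The package implements three estimators behind one
fitting interface:

* **INT** — sample-by-sample exact (constant-rate) integration of the
  kinematic equation; the drifting baseline.
* **SF** — a ten-state extended Kalman filter (quaternion, gyro bias,
  global-frame magnetic disturbance) with vector-selection gating: an
  accelerometer sample is used only when its magnitude is close to 1 g, a
  magnetometer sample only when its magnitude and dip angle match the local
  reference field.
* **CF** — a complementary filter: the gyro-driven quaternion derivative is
  corrected by one normalized gradient-descent step on an
  accelerometer+magnetometer objective, scaled by the single gain β
  (default 0.1 rad/s = 5.73 °/s, β = √(3/4)·ω̃_max with ω̃_max three times
  the gyro noise SD).

Accuracy against a reference orientation is summarized by the error
quaternion Δq̄, its total angle Δθ = 2·cos⁻¹|Δq₄|, and the swing-twist
decomposition of Δq̄ about the vertical axis into a heading error
(`RMS_head`) and an attitude error (`RMS_att`).

Around the estimators the package provides the standard pipeline:
cubic-spline resampling, zero-lag Butterworth low-pass filtering with
Winter-style residual-analysis cutoff selection, static gyro-bias
estimation, a three-orientation accelerometer calibration check, and
axis-aligned magnetometer ellipsoid calibration (hard-iron bias + per-axis
sensitivity). A synthetic-data module generates ground-truth rigid-body
motion for two motor scenarios — a 60 s seated *manual routine* (static
pauses, ≈120° rotations about each sensor axis, an optional 200 μT magnet
event) and a 180 s figure-of-eight *locomotion* trial (≈260° heading
excursion, roll/pitch under 10°, gait accelerations, slow spatial field
variation) — and synthesizes MIMU measurements with configurable noise,
bias, hard iron and sensitivity errors, so the whole pipeline runs without
any recorded data.

## Worked example

Simulate a manual-routine trial with a biased, noisy sensor, estimate the
bias from a one-minute static acquisition, and fit the EKF:

```r
library(mimufusion)

truth  <- make_manual_routine(seed = 1)
model  <- sensor_model(gyro_bias = c(0.3, -0.2, 0.4))   # deg/s
trace  <- synthesize_trace(truth, model, seed = 11)
static <- make_static_trace(60, model, seed = 99)
bias   <- estimate_gyro_bias(static)
round(bias, 3)
#> [1]  0.318 -0.220  0.333

fit <- fit_orientation(trace, method = "sf", params = sf_params("manual"),
                       gyro_bias = bias, reference = truth$orientation)
summary(fit)
#> Orientation fit (SF): 7680 samples over 60.0 s
#>   excursion: yaw 85.2 deg, pitch 80.2 deg, roll 95.2 deg
#>   accuracy vs reference: RMS_head 0.70 deg, RMS_att 0.70 deg, RMS 0.99 deg
```

The bias estimate recovers the injected (0.3, −0.2, 0.4) °/s to within the
sampling error of the static acquisition, and the EKF tracks the 60 s
trial with sub-degree heading and attitude RMS errors. Pure integration on
the same trace is noticeably worse, mostly from the residual bias and the
gyro noise random walk:

```r
fit_int <- fit_orientation(trace, method = "int", gyro_bias = bias,
                           reference = truth$orientation)
round(rms_summary(residuals(fit_int)), 2)
#>  rms_head   rms_att rms_total
#>      1.51      1.79      2.35
```

`residuals()` returns the full per-sample error series, `plot(fit)` draws
the Euler-angle trajectories, and `run_benchmark()` repeats the whole
generate–synthesize–calibrate–estimate–evaluate pipeline over seeded trials
and tabulates per-method `RMS_head` / `RMS_att`.

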