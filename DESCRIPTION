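Package: mimufusion
Title: Orientation Estimation from Magnetic and Inertial Measurement Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quaternion-based 3-D orientation estimation for magnetic and
    inertial measurement units (MIMUs) worn on body segments, and tools to
    assess estimator accuracy. Implements strapdown numerical integration of
    the quaternion kinematic equation, a ten-state extended Kalman filter with
    accelerometer/magnetometer vector-selection gating and online magnetic
    disturbance estimation, and a gradient-descent complementary filter.
    Includes sensor calibration and signal-conditioning utilities (zero-lag
    Butterworth filtering with residual-analysis cutoff selection, static gyro
    bias estimation, axis-aligned magnetometer ellipsoid calibration), a
    synthetic generator of ground-truth rigid-body motion and MIMU
    measurements emulating manual-task and figure-of-eight locomotion
    scenarios, and heading/attitude error metrics based on the swing-twist
    decomposition of the error quaternion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
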