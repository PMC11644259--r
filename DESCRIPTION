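Package: gaitvar
Title: Linear and Nonlinear Gait Variability Metrics from a Single
    Trunk Accelerometer
Version: 0.1.0
Authors@R:
    person("ACIER", "Toolkit Authors", email = "gaitvar@example.org",
           role = c("aut", "cre"))
Description: Computes gait variability metrics from raw triaxial
    accelerometer recordings taken at the lower back (and optionally the
    foot) during steady walking.  Covers walking-bout segmentation,
    tilt calibration of the sensor frame, standardization of bouts to a
    fixed step count, movement intensity (RMS and RMS ratio), step and
    stride regularity from the unbiased autocorrelation function, local
    dynamic stability and the attractor complexity index from Rosenstein
    divergence curves of delay-embedded signals, and detrended
    fluctuation analysis of stride-interval series.  A seeded synthetic
    generator produces gait-like signals with controllable
    stride-interval correlation structure so every stage is testable
    without sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
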