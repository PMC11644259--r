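test_that("step frequency is recovered from tones and gait, and fails on noise", {
  fs <- 256
  t <- seq(0, 120, by = 1 / fs)
  est <- estimate_step_frequency(sin(2 * pi * 2.0 * t), fs)
  expect_lt(abs(est$sf - 2.0), 0.005)
  expect_false(est$edge_peak)

  seg_src <- synth_spec(n_strides = 130, seed = 31)
  tr <- gen_trunk_accel(gen_stride_series(seg_src), seg_src)
  cal <- calibrate_tilt(tr)
  est2 <- estimate_step_frequency(cal$v, cal$fs)
  expect_lt(abs(est2$sf - 1.9), 0.01)

  set.seed(1)
  expect_error(estimate_step_frequency(rnorm(120 * fs), fs), "dominant")
  expect_error(estimate_step_frequency(sin(2 * pi * 2 * t[1:100]), fs),
               "30 s")
})

test_that("truncation keeps round(n_steps / sf * fs) samples", {
  mk <- function(n) calibrated_signals(seq_len(n) * 0, rep(1, n),
                                       rep(0, n), rep(0, n), fs = 256)
  tr <- truncate_to_steps(mk(40000), sf = 2.0)
  expect_length(tr$ap, 32000L)
  tr2 <- truncate_to_steps(mk(40000), sf = 1.9)
  expect_length(tr2$ap, 33684L)          # round(250 / 1.9 * 256)
  expect_error(truncate_to_steps(mk(10000), sf = 2.0), "short by")
})

test_that("resampling lands on 18,750 samples, is identity on-grid, preserves RMS", {
  n <- 33684
  x <- sin(2 * pi * 1.9 * (0:(n - 1)) / 256)
  cs <- calibrated_signals(x, x, x, x, fs = 256)
  seg <- resample_to_standard(cs, sf = 1.9)
  expect_length(seg$ap, 18750L)
  expect_identical(seg$samples_per_stride, 150L)
  # RMS of a pure sine survives the grid change to 0.1%
  expect_lt(abs(sqrt(mean(seg$ap^2)) / sqrt(mean(x^2)) - 1), 1e-3)

  y <- rnorm(18750)
  cs2 <- calibrated_signals(y, y, y, y, fs = 256)
  seg2 <- resample_to_standard(cs2, sf = 2.0)
  expect_lt(max(abs(seg2$ap - y)), 1e-9)
})

test_that("standardized gait has its step period at 75 samples", {
  seg <- make_segment(seed = 33)
  # spectrum of the standardized V axis must peak at 1/75 cycles/sample
  v <- seg$v - mean(seg$v)
  mag <- Mod(fft(v))[2:9375]
  k_peak <- which.max(mag)
  expect_equal(k_peak, 250L, tolerance = 1)   # 18750 / 75 = 250th bin
})
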