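test_that("stride detection recovers generator ground truth", {
  sp <- synth_spec(n_strides = 125, seed = 7)
  st <- gen_stride_series(sp)
  ft <- gen_foot_accel(st, sp)
  det <- detect_strides(ft)
  gt <- attr(ft, "ground_truth")
  expect_equal(det$n, 125L)
  expect_lte(max(abs(det$intervals - gt$intervals)) * sp$fs, 2)

  # noiseless world: detection exact to the sample
  sp0 <- synth_spec(n_strides = 80, seed = 8, noise_sd = 0)
  ft0 <- gen_foot_accel(gen_stride_series(sp0), sp0)
  det0 <- detect_strides(ft0)
  expect_identical(det0$source_peaks, attr(ft0, "ground_truth")$peak_idx)

  quiet <- accel_trace(rep(0, 256 * 60), rep(1, 256 * 60), rep(0, 256 * 60),
                       fs = 256, site = "foot")
  expect_error(detect_strides(quiet), "strides detected")
})

test_that("DFA hits the white-noise and random-walk limits (200-rep oracles)", {
  set.seed(11)
  aw <- replicate(200, dfa(rnorm(512))$alpha)
  ar <- replicate(200, dfa(cumsum(rnorm(512)))$alpha)
  expect_lt(abs(mean(aw) - 0.50), 0.05)
  expect_lt(abs(mean(ar) - 1.50), 0.07)
})

test_that("DFA is shift invariant and scale equivariant", {
  sp <- synth_spec(n_strides = 256, target_alpha = 0.8, seed = 13)
  x <- gen_stride_series(sp)$intervals
  r0 <- dfa(x)
  r_shift <- dfa(x + 5)
  expect_equal(r_shift$alpha, r0$alpha, tolerance = 1e-9)
  expect_equal(r_shift$fluctuations, r0$fluctuations, tolerance = 1e-9)
  r_scale <- dfa(x * 4)
  expect_equal(r_scale$alpha, r0$alpha, tolerance = 1e-9)
  expect_equal(r_scale$fluctuations, 4 * r0$fluctuations, tolerance = 1e-9)
  expect_gte(r0$fit_r2, 0.9)
  expect_true(all(r0$box_sizes >= 16 & r0$box_sizes <= 128))
})

test_that("DFA recovers imposed scaling exponents across the alpha range", {
  for (a in c(0.3, 0.5, 0.8, 1.0)) {
    rec <- vapply(1:200, function(i) {
      sp <- synth_spec(n_strides = 512, target_alpha = a,
                       seed = as.integer(1000 * a) + i)
      dfa(gen_stride_series(sp))$alpha
    }, numeric(1))
    expect_lt(abs(mean(rec) - a), 0.1)
  }
})

test_that("persistence classification follows the stated bounds", {
  expect_identical(classify_persistence(0.74), "persistent")
  expect_identical(classify_persistence(0.39), "anti-persistent")
  expect_identical(classify_persistence(0.6), "indeterminate")
  expect_identical(classify_persistence(1.2), "indeterminate")
  expect_error(classify_persistence(NaN), "finite")
})

test_that("stride series round-trip through delimited text", {
  sp <- synth_spec(n_strides = 100, seed = 17)
  st <- gen_stride_series(sp)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_stride_series(st, f)
  st2 <- read_stride_series(f)
  expect_identical(st2$intervals, st$intervals)
})

test_that("degenerate series are refused", {
  expect_error(dfa(rnorm(32)), "at least 64")
  expect_error(dfa(rep(1, 128)), "degenerate")
})
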