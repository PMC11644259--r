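mk_seg <- function(norm, ml = norm, ap = norm, v = norm) {
  standardized_segment(ap = ap, v = v, ml = ml, norm = norm, sf = 1.9)
}

test_that("movement intensity matches analytic RMS and the ratio contract", {
  x <- sin(2 * pi * (0:18749) / 75)
  a <- 0.37
  seg <- mk_seg(norm = a * x, ml = a * x)
  mi <- movement_intensity(seg)
  expect_equal(mi$rms_norm, a / sqrt(2), tolerance = 1e-6)
  expect_equal(mi$rms_ratio, 1.0, tolerance = 1e-12)

  # generator calibration: ML amplitude tuned for a cohort-scale RMS ratio
  seg2 <- make_segment(seed = 41)
  mi2 <- movement_intensity(seg2)
  expect_lt(abs(mi2$rms_ratio - 0.65), 0.02)
  expect_gt(mi2$rms_norm, 0.2); expect_lt(mi2$rms_norm, 0.4)
})

test_that("acf regularity is exact for periodic signals and Fisher-transforms", {
  x <- rep(sin(2 * pi * (0:74) / 75) + 0.3 * sin(4 * pi * (0:74) / 75), 250)
  rg <- acf_regularity(mk_seg(x))
  expect_equal(rg$step_regularity_r, 1.0, tolerance = 1e-9)
  expect_equal(rg$stride_regularity_r, 1.0, tolerance = 1e-9)
  expect_equal(rg$step_lag, 75L)
  # r = 1 clamps to atanh(1 - 1e-12)
  expect_equal(rg$step_regularity_z, atanh(1 - 1e-12))
  expect_equal(atanh(0.8), 1.0986, tolerance = 1e-4)

  # amplitude scaling leaves the normalized ACF untouched
  seg <- make_segment(seed = 43)
  r1 <- acf_regularity(seg)
  seg_scaled <- seg
  for (f in c("ap", "v", "ml", "norm")) seg_scaled[[f]] <- 7.3 * seg[[f]]
  r2 <- acf_regularity(seg_scaled)
  expect_equal(r2$step_regularity_r, r1$step_regularity_r, tolerance = 1e-9)
  expect_equal(r2$stride_regularity_r, r1$stride_regularity_r, tolerance = 1e-9)
})

test_that("white-noise regularity is near zero (null simulation)", {
  set.seed(99)
  rs <- replicate(200, {
    rg <- acf_regularity(mk_seg(rnorm(18750)))
    c(rg$step_regularity_r, rg$stride_regularity_r)
  })
  expect_lt(max(abs(rs)), 0.2)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("added noise monotonically lowers mean step regularity", {
  reg_at <- function(noise) {
    mean(vapply(1:50, function(i) {
      seg <- make_segment(seed = 500 + i, n_strides = 135, noise_sd = noise)
      acf_regularity(seg)$step_regularity_r
    }, numeric(1)))
  }
  m <- vapply(c(0, 0.03, 0.08), reg_at, numeric(1))
  expect_true(all(diff(m) < 0))
})
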