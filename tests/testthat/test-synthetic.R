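test_that("stride series honor the rescaling contract and are seed-deterministic", {
  sp <- synth_spec(n_strides = 512, target_alpha = 0.9, mean_stride_s = 1.05,
                   sd_stride_s = 0.02, seed = 7)
  st <- gen_stride_series(sp)
  expect_lt(abs(mean(st$intervals) - 1.05), 0.005)
  expect_lt(abs(sd(st$intervals) - 0.02), 0.004)
  st2 <- gen_stride_series(sp)
  expect_identical(st$intervals, st2$intervals)

  expect_error(synth_spec(n_strides = 100), "seed")
  expect_error(synth_spec(target_alpha = 1.7, seed = 1), "target_alpha")
  expect_error(synth_spec(sd_stride_s = 0.5, seed = 1), "sd_stride_s")
})

test_that("alpha = 0.5 behaves as white noise; alpha = 0.25 is anti-correlated", {
  rho1 <- function(a, i) {
    s <- gen_stride_series(synth_spec(n_strides = 512, target_alpha = a,
                                      seed = i))$intervals
    cor(s[-1], s[-512])
  }
  r_white <- vapply(1:200, function(i) rho1(0.5, i), numeric(1))
  expect_lt(abs(mean(r_white)), 0.02)
  expect_lt(mean(abs(r_white)), 0.1)
  expect_gte(mean(abs(r_white) <= 0.1), 0.95)

  r_anti <- vapply(1:200, function(i) rho1(0.25, i), numeric(1))
  expect_gte(mean(r_anti < 0), 0.95)
})

test_that("trunk traces are periodic when noiseless and seed-deterministic", {
  sp <- synth_spec(n_strides = 135, seed = 23, noise_sd = 0,
                   sd_stride_s = 1e-9, amp_jitter_cv = 0, tilt = 0,
                   tilt_frontal = 0)
  expect_no_warning(st <- gen_stride_series(sp))
  tr <- gen_trunk_accel(st, sp)
  seg <- standardize_bout(calibrate_tilt(tr))
  rg <- acf_regularity(seg)
  expect_gt(rg$step_regularity_r, 0.999)

  sp2 <- synth_spec(n_strides = 70, seed = 29)
  t1 <- gen_trunk_accel(gen_stride_series(sp2), sp2)
  t2 <- gen_trunk_accel(gen_stride_series(sp2), sp2)
  expect_identical(t1$ay, t2$ay)
})

test_that("foot traces carry one spike per stride boundary (fencepost)", {
  sp <- synth_spec(n_strides = 125, seed = 25)
  ft <- gen_foot_accel(gen_stride_series(sp), sp)
  gt <- attr(ft, "ground_truth")
  expect_length(gt$peak_idx, 126L)
  expect_true(all(ft$ay[gt$peak_idx + 1L] > 3))
})

test_that("Lorenz oracle: Benettin exponent in the canonical regime", {
  l1 <- cached("benettin_dt01", benettin_lyapunov(dt = 0.01, n = 40000))
  expect_lt(abs(l1 - 0.9) / 0.9, 0.05)
  # integration convergence: halving dt moves the estimate by < 2%
  l1h <- benettin_lyapunov(dt = 0.005, n = 80000, skip = 2000)
  expect_lt(abs(l1h - l1) / l1, 0.02)
  # fixed-point regime contracts
  l_fp <- benettin_lyapunov(state0 = c(1, 1, 1), rho = 0.5, n = 5000)
  expect_lt(l_fp, 0)
})
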