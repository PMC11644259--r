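test_that("delay embedding builds the attractor rows stated by the formula", {
  expect_equal(embed_delay(c(1, 2, 3, 4), m = 2, tau = 1),
               rbind(c(1, 2), c(2, 3), c(3, 4)))
  att <- embed_delay(rnorm(18750), m = 6, tau = 15)
  expect_equal(nrow(att), 18675L)
  expect_true(all(embed_delay(rep(2, 100), m = 3, tau = 5) == 2))
  expect_error(embed_delay(1:10, m = 1, tau = 1), "m >= 2")
  expect_error(embed_delay(1:10, m = 6, tau = 15), "too short")
})

test_that("divergence of near-parallel trajectories is flat and runs are deterministic", {
  # incommensurate period just past the Theiler window: every point's
  # neighbour is a phase twin some cycles away, and the pair never
  # separates (a rationally commensurate period would make the attractor
  # repeat exactly and collapse all distances to float noise)
  x <- sin(2 * pi * (0:2999) / 151.618034)
  att <- embed_delay(x, m = 2, tau = 38)
  cur <- rosenstein_divergence(att, samples_per_stride = 150,
                               t_max_strides = 2, theiler_w = 150)
  fe <- fit_exponents(cur, lds_window = c(0, 0.5), aci_window = c(1, 2))
  expect_lt(abs(fe$lds), 0.02)   # vs ~0.4 nats/stride on synthetic gait
  expect_lt(abs(fe$aci), 0.02)

  cur2 <- rosenstein_divergence(att, samples_per_stride = 150,
                                t_max_strides = 2, theiler_w = 150)
  expect_identical(cur$d, cur2$d)
})

test_that("white-noise attractors saturate: long-range slope below short-range", {
  set.seed(7)
  for (i in 1:20) {
    att <- embed_delay(rnorm(6000), m = 6, tau = 15)
    cur <- rosenstein_divergence(att, samples_per_stride = 150,
                                 t_max_strides = 12.5, theiler_w = 150)
    fe <- fit_exponents(cur)
    expect_lt(fe$aci, fe$lds)
  }
})

test_that("exponent fits are exact on synthetic curves", {
  tt <- seq(0, 12.5, by = 1 / 150)
  mk_curve <- function(d) structure(list(t = tt, d = d,
                                         n_pairs = rep(100L, length(tt))),
                                    class = "divergence_curve")
  fe <- fit_exponents(mk_curve(0.02 * tt))
  expect_equal(fe$lds, 0.02, tolerance = 1e-9)
  expect_equal(fe$aci, 0.02, tolerance = 1e-9)

  # knee curve at cohort-scale magnitudes: steep early rise, shallow tail
  d2 <- ifelse(tt < 1, 1.2 * tt, 1.2 + 0.025 * (tt - 1))
  fe2 <- fit_exponents(mk_curve(d2))
  expect_equal(fe2$lds, 1.2, tolerance = 1e-6)
  expect_equal(fe2$aci, 0.025, tolerance = 1e-6)

  fe3 <- fit_exponents(mk_curve(rep(1.5, length(tt))))
  expect_equal(fe3$lds, 0, tolerance = 1e-12)
  expect_equal(fe3$aci, 0, tolerance = 1e-12)

  expect_error(fit_exponents(mk_curve(0 * tt), aci_window = c(5, 20)),
               "window")
})

test_that("exponents are invariant under amplitude scaling", {
  seg <- make_segment(seed = 51)
  r1 <- compute_lds_aci(seg, axes = c("ml", "ap"))
  seg3 <- seg
  for (f in c("ap", "v", "ml", "norm")) seg3[[f]] <- 3 * seg[[f]]
  r2 <- compute_lds_aci(seg3, axes = c("ml", "ap"))
  expect_equal(r2$lds_ml, r1$lds_ml, tolerance = 1e-9)
  expect_equal(r2$aci_ap, r1$aci_ap, tolerance = 1e-9)
})

test_that("a deterministic periodic ML axis has near-zero LDS", {
  x <- sin(2 * pi * (0:18749) / 149.618034)
  seg <- standardized_segment(ap = x, v = x, ml = x, norm = x, sf = 1.9)
  r <- compute_lds_aci(seg, axes = "ml")
  expect_lt(abs(r$lds_ml), 0.05)
})

test_that("ACI responds to imposed stride-interval structure (50 paired runs)", {
  res <- pair_suite()
  d <- res[, "p"] - res[, "a"]
  expect_gte(mean(res[, "a"] < res[, "p"]), 0.9)
  expect_gte(mean(d) / sd(d), 0.5)       # standardized paired effect
})
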