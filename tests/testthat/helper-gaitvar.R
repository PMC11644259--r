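# Shared fixtures and independent oracles.  Everything is generated in code;
# expensive simulations are cached for the session so several test files can
# assert against the same run.

.gv_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .gv_test_cache)) {
    assign(key, force(expr), envir = .gv_test_cache)
  }
  get(key, envir = .gv_test_cache)
}

# one synthetic lumbar segment through the standard pipeline
make_segment <- function(alpha = 0.9, seed = 1, n_strides = 132, ...) {
  sp <- synth_spec(n_strides = n_strides, target_alpha = alpha,
                   seed = seed, ...)
  st <- gen_stride_series(sp)
  tr <- gen_trunk_accel(st, sp)
  standardize_bout(calibrate_tilt(tr))
}

# random 3-D rotation matrix from a seed (QR of a Gaussian matrix)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Benettin variational oracle for the maximal Lyapunov exponent of the
# Lorenz system: integrates the tangent map alongside the trajectory with
# the same RK4 scheme and renormalizes every step.  Independent of the
# Rosenstein path under test.
benettin_lyapunov <- function(state0 = c(1, 1, 20), dt = 0.01, n = 40000,
                              skip = 1000, sigma = 10, rho = 28, beta = 8 / 3) {
  f <- function(s) c(sigma * (s[2] - s[1]),
                     s[1] * (rho - s[3]) - s[2],
                     s[1] * s[2] - beta * s[3])
  Jv <- function(s, v) c(-sigma * v[1] + sigma * v[2],
                         (rho - s[3]) * v[1] - v[2] - s[1] * v[3],
                         s[2] * v[1] + s[1] * v[2] - beta * v[3])
  s <- state0; v <- c(1, 0, 0); acc <- 0; cnt <- 0
  for (i in seq_len(n)) {
    k1 <- f(s); l1 <- Jv(s, v)
    k2 <- f(s + dt / 2 * k1); l2 <- Jv(s + dt / 2 * k1, v + dt / 2 * l1)
    k3 <- f(s + dt / 2 * k2); l3 <- Jv(s + dt / 2 * k2, v + dt / 2 * l2)
    k4 <- f(s + dt * k3);     l4 <- Jv(s + dt * k3, v + dt * l3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    v <- v + dt / 6 * (l1 + 2 * l2 + 2 * l3 + l4)
    g <- sqrt(sum(v * v)); v <- v / g
    if (i > skip) { acc <- acc + log(g); cnt <- cnt + 1 }
  }
  acc / (cnt * dt)
}

# 50 paired persistent / anti-persistent pipeline runs (fixed seeds);
# shared by the responsiveness property and the paper-anchored acceptance
# criterion.  Roughly 2.5 minutes of compute, done once per session.
pair_suite <- function() {
  cached("pair_suite", {
    t(vapply(1:50, function(i) {
      one <- function(alpha) {
        seg <- make_segment(alpha = alpha, seed = 1000L + i)
        compute_lds_aci(seg, axes = "ap")$aci_ap
      }
      c(p = one(0.9), a = one(0.25))
    }, c(p = 0, a = 0)))
  })
}

# rest | walk | rest trace with ground-truth walking span (0-based indices)
make_rest_walk_rest <- function(seed, walk_s = 75, rest1_s = 15, rest2_s = 15,
                                fs = 256) {
  sp <- synth_spec(n_strides = ceiling(walk_s / 1.05), seed = seed)
  st <- gen_stride_series(sp)
  tr <- gen_trunk_accel(st, sp)
  n_walk <- length(tr$ax)
  set.seed(seed + 90000L)
  mk_rest <- function(sec) {
    n <- round(sec * fs)
    cbind(rnorm(n, 0, 0.003), rnorm(n, 1, 0.003), rnorm(n, 0, 0.003))
  }
  r1 <- mk_rest(rest1_s); r2 <- mk_rest(rest2_s)
  full <- accel_trace(ax = c(r1[, 1], tr$ax, r2[, 1]),
                      ay = c(r1[, 2], tr$ay, r2[, 2]),
                      az = c(r1[, 3], tr$az, r2[, 3]), fs = fs)
  list(trace = full, walk_start = nrow(r1), walk_end = nrow(r1) + n_walk)
}
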