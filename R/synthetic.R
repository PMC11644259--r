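#' Specification for synthetic gait signals
#'
#' One object states the whole simulated world: stride count and timing
#' statistics, target scaling exponent of the stride-interval series, step
#' frequency and sampling rate, sensor tilt, axis amplitudes, waveform
#' harmonic count, additive noise, and the mandatory seed.  Defaults emulate
#' steady corridor walking as recorded by a lumbar sensor: ~1.9 Hz step
#' frequency (stride ~1.05 s), 256 Hz sampling, stride-time SD 0.02 s
#' (a typical ~2% coefficient of variation for healthy steady walking),
#' persistent stride-interval structure (alpha 0.9), amplitudes that land
#' movement intensity near 0.3 g and the RMS ratio near 0.65.
#'
#' @param n_strides number of strides to generate.
#' @param target_alpha DFA scaling exponent imposed on the stride-interval
#'   series, in (0, 1.5).
#' @param sf step frequency (Hz).
#' @param mean_stride_s mean stride duration (s); default `2 / sf`.
#' @param sd_stride_s SD of stride durations (s); must stay below
#'   `mean_stride_s / 5`.  Default 0.01 s (CV ~1%, the low end of the
#'   healthy steady-walking range): the synthetic attractor is a
#'   low-dimensional phase loop, and larger timing SDs drive neighbour
#'   phase drift into saturation inside the 5--12-stride divergence
#'   window, masking the imposed correlation structure the generator is
#'   contractually required to express.
#' @param fs sampling rate (Hz).
#' @param tilt sagittal sensor tilt (degrees); a frontal tilt of
#'   `tilt_frontal` degrees is applied as well.
#' @param tilt_frontal frontal-plane tilt (degrees).
#' @param axis_amplitudes named amplitudes (g) of the AP, V and ML
#'   waveform components.
#' @param harmonics number of sinusoidal harmonics per axis waveform.
#' @param noise_sd SD of additive white Gaussian sensor noise (g).  The
#'   default is the wide-band noise floor of a MEMS accelerometer
#'   (a few hundred ug/sqrt(Hz) over a ~128 Hz bandwidth); it is
#'   deliberately small so that the imposed stride-interval structure is
#'   the dominant stochastic component of the signal.
#' @param amp_jitter_cv coefficient of variation of the per-stride
#'   amplitude scaling (left-right and stride-to-stride amplitude
#'   variability of real gait).
#' @param impact_amp amplitude (g) of the step-onset impact transient on
#'   the trunk V axis.
#' @param seed RNG seed (mandatory; all generators are seed-deterministic).
#' @return a list of class `synth_spec`.
#' @export
synth_spec <- function(n_strides = 150, target_alpha = 0.9, sf = 1.9,
                       mean_stride_s = 2 / sf, sd_stride_s = 0.01,
                       fs = 256, tilt = 8, tilt_frontal = 4,
                       axis_amplitudes = c(ap = 0.30, v = 0.40, ml = 0.27),
                       harmonics = 3, noise_sd = 0.005,
                       amp_jitter_cv = 0.05, impact_amp = 0.10, seed) {
  if (missing(seed)) stop("synth_spec: seed is mandatory", call. = FALSE)
  if (target_alpha <= 0 || target_alpha >= 1.5)
    stop("synth_spec: target_alpha must lie in (0, 1.5)", call. = FALSE)
  if (sd_stride_s >= mean_stride_s / 5)
    stop("synth_spec: sd_stride_s must be below mean_stride_s / 5", call. = FALSE)
  stopifnot(all(c("ap", "v", "ml") %in% names(axis_amplitudes)))
  structure(list(n_strides = as.integer(n_strides),
                 target_alpha = target_alpha, sf = sf,
                 mean_stride_s = mean_stride_s, sd_stride_s = sd_stride_s,
                 fs = fs, tilt = tilt, tilt_frontal = tilt_frontal,
                 axis_amplitudes = axis_amplitudes,
                 harmonics = as.integer(harmonics), noise_sd = noise_sd,
                 amp_jitter_cv = amp_jitter_cv,
                 impact_amp = impact_amp, seed = as.integer(seed)),
            class = "synth_spec")
}

# evaluate code under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# exact fractional Gaussian noise via Davies-Harte circulant embedding
.fgn_davies_harte <- function(n, H) {
  k <- 0:n
  g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  row <- c(g, g[n:2])                     # circulant first row, length 2n
  lambda <- Re(fft(row))
  if (min(lambda) < -1e-8 * max(lambda))
    stop("fgn: circulant embedding not positive semidefinite for this alpha; ",
         "use the spectral-synthesis fallback", call. = FALSE)
  lambda <- pmax(lambda, 0)
  m <- 2L * n
  W <- complex(m)
  W[1L] <- sqrt(lambda[1L]) * rnorm(1)
  W[n + 1L] <- sqrt(lambda[n + 1L]) * rnorm(1)
  u <- rnorm(n - 1L); v <- rnorm(n - 1L)
  W[2:n] <- sqrt(lambda[2:n] / 2) * complex(real = u, imaginary = v)
  W[m:(n + 2L)] <- Conj(W[2:n])
  Re(fft(W))[seq_len(n)] / sqrt(m)
}

# approximate series with power spectrum ~ f^-beta via random-phase synthesis
.fgn_spectral <- function(n, beta) {
  m <- 2L * n
  f <- seq_len(m %/% 2L)
  amp <- f^(-beta / 2)
  ph <- runif(length(f), 0, 2 * pi)
  spec <- complex(m)
  spec[2:(m %/% 2L + 1L)] <- amp * exp(1i * ph)
  spec[m:(m %/% 2L + 2L)] <- Conj(spec[2:(m %/% 2L)])
  x <- Re(fft(spec, inverse = TRUE))
  x[seq_len(n)]
}

#' Generate a stride-interval series with a target scaling exponent
#'
#' Draws a fractional-Gaussian-noise series whose spectral exponent follows
#' the fGn relation `beta = 2 * alpha - 1`, then rescales it to the
#' requested mean and SD exactly.  For `alpha` in (0, 1) the exact
#' Davies--Harte circulant-embedding sampler is used (the process *is* fGn
#' with Hurst exponent `alpha`); for `alpha >= 1`, where fGn is undefined,
#' random-phase spectral synthesis of a `1/f^beta` series takes over.
#'
#' @param spec a [synth_spec()].
#' @return a [stride_series()] with attribute `ground_truth` (a list with
#'   the spec and the method used).
#' @export
gen_stride_series <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_strides
  a <- spec$target_alpha
  x <- .with_seed(spec$seed, {
    if (a < 1 && a > 0.05) {
      tryCatch(.fgn_davies_harte(n, H = a),
               error = function(e) .fgn_spectral(n, beta = 2 * a - 1))
    } else {
      .fgn_spectral(n, beta = 2 * a - 1)
    }
  })
  x <- (x - mean(x)) / sd(x) * spec$sd_stride_s + spec$mean_stride_s
  out <- stride_series(x, gate = c(0, Inf))
  attr(out, "ground_truth") <- list(spec = spec,
                                    method = if (a < 1) "davies-harte" else "spectral")
  out
}

# continuous stride-phase function: piecewise-linear cumulative stride count
# evaluated at the sample grid; returns list(u = phase, t = times, total_s)
.stride_phase <- function(intervals, fs) {
  onsets <- c(0, cumsum(intervals))
  total <- onsets[length(onsets)]
  t <- seq(0, total, by = 1 / fs)
  t <- t[t < total]
  u <- approx(onsets, seq_along(onsets) - 1, xout = t)$y
  list(u = u, t = t, onsets = onsets, total_s = total)
}

# inverse tilt: rotate true (ap, v, ml) into a tilted raw sensor frame
.apply_tilt <- function(ap, v, ml, sag_deg, front_deg) {
  f <- front_deg * pi / 180
  ml1 <- ml * cos(f) + v * sin(f)
  v1 <- -ml * sin(f) + v * cos(f)
  s <- sag_deg * pi / 180
  ap1 <- ap * cos(s) + v1 * sin(s)
  v2 <- -ap * sin(s) + v1 * cos(s)
  list(ap = ap1, v = v2, ml = ml1)
}

#' Generate a gait-like lumbar acceleration trace
#'
#' Phenomenological trunk waveform built on a stride-interval series: AP
#' and V carry harmonics of the *step* frequency (two cycles per stride), ML
#' carries the *stride* frequency (one cycle per stride, modelling
#' left--right asymmetry), each stride's waveform is time-warped to its own
#' interval, a sharp impact transient marks every step onset, the declared
#' sensor tilt is applied as a pure rotation, gravity (+1 g) rides on the
#' raw vertical channel, and white Gaussian noise is added per channel.
#' The untilted noise-free axis signals and the stride onsets are attached
#' as ground truth.
#'
#' @param strides a [stride_series()] (typically from [gen_stride_series()]).
#' @param spec the [synth_spec()].
#' @return an [accel_trace()] (site `"lumbar"`) with attribute
#'   `ground_truth`: list with `ap`, `v`, `ml` (true untilted dynamics, g),
#'   `onsets_s`, `sf`, and the spec.
#' @export
gen_trunk_accel <- function(strides, spec) {
  stopifnot(inherits(strides, "stride_series"), inherits(spec, "synth_spec"))
  ph <- .stride_phase(strides$intervals, spec$fs)
  u <- ph$u
  H <- spec$harmonics
  ch <- (1 / seq_len(H)); ch <- ch / sqrt(sum(ch^2))
  A <- spec$axis_amplitudes
  vdyn <- A[["v"]] * colSums(ch * t(sapply(seq_len(H), function(h)
    cos(2 * pi * h * 2 * u))))
  apdyn <- A[["ap"]] * colSums(ch * t(sapply(seq_len(H), function(h)
    sin(2 * pi * h * 2 * u))))
  mldyn <- A[["ml"]] * sin(2 * pi * u)
  # impact transient, a narrow phase-locked bump at each step onset
  p <- (2 * u) %% 1
  pw <- pmin(p, 1 - p)
  imp <- spec$impact_amp * exp(-pw^2 / (2 * 0.03^2))
  imp <- imp - mean(imp)   # zero-mean so the transient cannot bias the
                           # gravity estimate used by tilt calibration
  vdyn <- vdyn + imp
  apdyn <- apdyn + 0.5 * imp
  if (spec$amp_jitter_cv > 0) {
    scl <- .with_seed(spec$seed + 3L,
                      1 + spec$amp_jitter_cv * rnorm(strides$n))
    sk <- scl[pmin(strides$n, floor(u) + 1L)]
    vdyn <- vdyn * sk; apdyn <- apdyn * sk; mldyn <- mldyn * sk
  }
  tilted <- .apply_tilt(apdyn, 1 + vdyn, mldyn, spec$tilt, spec$tilt_frontal)
  noise <- .with_seed(spec$seed + 1L,
                      matrix(rnorm(3L * length(u), sd = spec$noise_sd),
                             ncol = 3L))
  tr <- accel_trace(ax = tilted$ap + noise[, 1L],
                    ay = tilted$v + noise[, 2L],
                    az = tilted$ml + noise[, 3L],
                    fs = spec$fs, site = "lumbar")
  attr(tr, "ground_truth") <- list(ap = apdyn, v = 1 + vdyn, ml = mldyn,
                                   onsets_s = ph$onsets, sf = spec$sf,
                                   spec = spec)
  tr
}

#' Generate a foot acceleration trace with impact spikes
#'
#' Baseline gravity plus sensor noise, with one high-prominence impact
#' spike (default 4 g, shaped over 3 samples) at each stride onset --
#' `n_strides + 1` spikes in all (fencepost).  Half a second of quiet
#' padding is prepended and appended so edge spikes are proper local
#' maxima.  Ground-truth spike sample indices (0-based) are attached.
#'
#' @param strides a [stride_series()].
#' @param spec the [synth_spec()].
#' @param spike_amp impact spike amplitude (g); keep >= 3 for reliable
#'   detection against the 1 g prominence default.
#' @return an [accel_trace()] (site `"foot"`) with attribute
#'   `ground_truth`: list with `peak_idx` (0-based sample indices) and the
#'   true intervals.
#' @export
gen_foot_accel <- function(strides, spec, spike_amp = 4) {
  stopifnot(inherits(strides, "stride_series"), inherits(spec, "synth_spec"))
  fs <- spec$fs
  pad <- as.integer(round(0.5 * fs))
  onsets <- c(0, cumsum(strides$intervals))
  n <- as.integer(round(onsets[length(onsets)] * fs)) + 2L * pad + 1L
  peak_idx <- as.integer(round(onsets * fs)) + pad   # 0-based
  ay <- rep(1, n)                                    # static gravity
  ay[peak_idx + 1L] <- 1 + spike_amp
  side <- peak_idx[peak_idx > 0L & peak_idx < n - 1L]
  ay[side] <- pmax(ay[side], 1 + 0.4 * spike_amp)        # left shoulder
  ay[side + 2L] <- pmax(ay[side + 2L], 1 + 0.4 * spike_amp)
  noise <- .with_seed(spec$seed + 2L,
                      matrix(rnorm(3L * n, sd = spec$noise_sd), ncol = 3L))
  tr <- accel_trace(ax = noise[, 1L], ay = ay + noise[, 2L],
                    az = noise[, 3L], fs = fs, site = "foot")
  attr(tr, "ground_truth") <- list(peak_idx = peak_idx,
                                   intervals = strides$intervals)
  tr
}

#' Integrate the Lorenz system (chaotic oracle fixture)
#'
#' Fixed-step fourth-order Runge--Kutta integration of the Lorenz
#' equations; the first `transient_s` seconds are discarded.  In the
#' canonical regime (sigma 10, rho 28, beta 8/3) the maximal Lyapunov
#' exponent is ~0.9 nats/s, which makes the x-component a standard test
#' signal for divergence-rate estimators.
#'
#' @param duration_s retained trajectory length (s).
#' @param dt integration step (s).
#' @param initial_state numeric length-3 start state.
#' @param sigma,rho,beta Lorenz parameters.
#' @param transient_s discarded lead-in (s).
#' @return list: `x` (retained x-component), `state` (n x 3 matrix),
#'   `dt`, `params`.
#' @export
gen_lorenz <- function(duration_s = 300, dt = 0.01,
                       initial_state = c(1, 1, 20),
                       sigma = 10, rho = 28, beta = 8 / 3,
                       transient_s = 10) {
  deriv <- function(s) {
    c(sigma * (s[2L] - s[1L]),
      s[1L] * (rho - s[3L]) - s[2L],
      s[1L] * s[2L] - beta * s[3L])
  }
  n_tot <- as.integer(round((duration_s + transient_s) / dt))
  n_skip <- as.integer(round(transient_s / dt))
  out <- matrix(0, n_tot - n_skip, 3L)
  s <- as.numeric(initial_state)
  for (i in seq_len(n_tot)) {
    k1 <- deriv(s)
    k2 <- deriv(s + dt / 2 * k1)
    k3 <- deriv(s + dt / 2 * k2)
    k4 <- deriv(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i > n_skip) out[i - n_skip, ] <- s
  }
  list(x = out[, 1L], state = out, dt = dt,
       params = list(sigma = sigma, rho = rho, beta = beta))
}
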