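#' Step-frequency estimate
#'
#' @param sf step frequency (Hz).
#' @param spectrum_peak_power share of band power in the dominant peak bin.
#' @param band searched band (Hz).
#' @param edge_peak TRUE if the peak sat at a band edge (flagged, not fatal).
#' @return object of class `sf_estimate`.
#' @keywords internal
sf_estimate <- function(sf, spectrum_peak_power, band, edge_peak = FALSE) {
  structure(list(sf = sf, spectrum_peak_power = spectrum_peak_power,
                 band = band, edge_peak = edge_peak),
            class = "sf_estimate")
}

#' Estimate step frequency from the vertical acceleration spectrum
#'
#' Locates the dominant frequency of the magnitude spectrum (FFT of the
#' mean-centred signal) inside `band` and refines it by parabolic
#' interpolation of the log magnitude around the peak bin.  A spectrum with
#' no dominant peak (peak bin carrying less than `min_peak_share` of the
#' band power) raises an estimation error; a peak at a band edge is flagged
#' via the `edge_peak` field.
#'
#' @param v_signal vertical-axis acceleration (or any signal with a
#'   dominant locomotor harmonic), at least 30 s long.
#' @param fs sampling rate (Hz).
#' @param band search band (Hz); default 1.2--3.0, the plausible human
#'   step-frequency range for steady walking.
#' @param min_peak_share dominance threshold (share of band power).
#' @return an `sf_estimate` with fields `sf`, `spectrum_peak_power`,
#'   `band`, `edge_peak`.
#' @export
estimate_step_frequency <- function(v_signal, fs, band = c(1.2, 3.0),
                                    min_peak_share = 0.1) {
  n <- length(v_signal)
  if (n / fs < 30)
    stop("estimate_step_frequency: need at least 30 s of signal", call. = FALSE)
  x <- v_signal - mean(v_signal)
  mag <- Mod(fft(x))[seq_len(n %/% 2L + 1L)]
  freq <- (seq_len(n %/% 2L + 1L) - 1L) * fs / n
  in_band <- which(freq >= band[1] & freq <= band[2])
  if (length(in_band) < 3L)
    stop("estimate_step_frequency: search band too narrow for this signal length",
         call. = FALSE)
  pw <- mag[in_band]^2
  tot <- sum(pw)
  if (tot <= 0)
    stop("estimate_step_frequency: flat spectrum", call. = FALSE)
  k <- in_band[which.max(pw)]
  share <- max(pw) / tot
  if (share < min_peak_share)
    stop("estimate_step_frequency: no dominant spectral peak in band",
         call. = FALSE)
  edge <- k == in_band[1L] || k == in_band[length(in_band)]
  # parabolic refinement on log magnitude (exact for a Gaussian-shaped peak,
  # excellent for the sinc mainlobe of a windowless FFT)
  if (k > 1L && k < length(mag)) {
    a <- log(mag[k - 1L]); b <- log(mag[k]); cc <- log(mag[k + 1L])
    den <- a - 2 * b + cc
    delta <- if (is.finite(den) && den != 0) 0.5 * (a - cc) / den else 0
    delta <- max(-0.5, min(0.5, delta))
  } else delta <- 0
  sf_estimate(sf = (k - 1L + delta) * fs / n,
              spectrum_peak_power = share, band = band, edge_peak = edge)
}

#' Truncate calibrated signals to a fixed step count
#'
#' Keeps the first `round(n_steps / sf * fs)` samples of every axis: the
#' span covering `n_steps` steps at the bout's own step frequency.
#' Rounding is half-away-from-zero to the nearest sample.
#'
#' @param signals a [calibrated_signals()].
#' @param sf step frequency (Hz) or an `sf_estimate`.
#' @param n_steps desired step count (default 250).
#' @return a [calibrated_signals()] of the truncated length.
#' @export
truncate_to_steps <- function(signals, sf, n_steps = 250) {
  stopifnot(inherits(signals, "calibrated_signals"))
  if (inherits(sf, "sf_estimate")) sf <- sf$sf
  need <- floor(n_steps / sf * signals$fs + 0.5)
  n <- length(signals$ap)
  if (n < need)
    stop(sprintf("truncate_to_steps: bout has %d samples but %d steps at %.3f Hz need %d (short by %d)",
                 n, n_steps, sf, need, need - n), call. = FALSE)
  idx <- seq_len(need)
  out <- calibrated_signals(signals$ap[idx], signals$v[idx],
                            signals$ml[idx], signals$norm[idx], signals$fs)
  attr(out, "sf") <- sf
  attr(out, "n_steps") <- n_steps
  out
}

#' Standardized analysis segment
#'
#' A walking bout truncated to a fixed step count and resampled to a fixed
#' grid: `n_steps * samples_per_step` samples per axis (default 250 x 75 =
#' 18,750), so one step spans 75 samples and one stride 150 regardless of
#' the walker's cadence.  All downstream metrics operate on this grid.
#'
#' @param ap,v,ml,norm resampled axis signals.
#' @param sf step frequency of the source bout (Hz).
#' @param samples_per_step samples per step on the standardized grid.
#' @param meta named list of labels (participant, condition, segment, ...).
#' @return object of class `standardized_segment`.
#' @export
standardized_segment <- function(ap, v, ml, norm, sf,
                                 samples_per_step = 75, meta = list()) {
  n <- length(ap)
  if (length(v) != n || length(ml) != n || length(norm) != n)
    stop("standardized_segment: axis lengths differ", call. = FALSE)
  structure(list(ap = ap, v = v, ml = ml, norm = norm, sf = sf,
                 samples_per_step = as.integer(samples_per_step),
                 samples_per_stride = 2L * as.integer(samples_per_step),
                 meta = meta),
            class = "standardized_segment")
}

#' @export
length.standardized_segment <- function(x) length(x$ap)

#' @export
print.standardized_segment <- function(x, ...) {
  cat(sprintf("<standardized_segment> n=%d (%d/step, %d/stride) sf=%.3f Hz\n",
              length(x$ap), x$samples_per_step, x$samples_per_stride, x$sf))
  invisible(x)
}

#' Resample truncated signals onto the standardized grid
#'
#' Interpolates each axis of a [truncate_to_steps()] output onto
#' `n_steps * samples_per_step` uniformly spaced points spanning the same
#' time interval.  Cubic-spline interpolation by default (smooth, no phase
#' distortion on band-limited gait signals); `method = "linear"` is
#' available.  The vector norm is resampled as a signal in its own right,
#' not recomputed from the resampled axes.
#'
#' @param truncated a [calibrated_signals()] from [truncate_to_steps()].
#' @param sf step frequency (Hz); defaults to the value recorded by
#'   [truncate_to_steps()].
#' @param n_steps,samples_per_step grid geometry (defaults 250 and 75).
#' @param method `"spline"` (default) or `"linear"`.
#' @param meta label list carried into the segment.
#' @return a [standardized_segment()].
#' @export
resample_to_standard <- function(truncated, sf = attr(truncated, "sf"),
                                 n_steps = 250, samples_per_step = 75,
                                 method = c("spline", "linear"),
                                 meta = list()) {
  stopifnot(inherits(truncated, "calibrated_signals"))
  method <- match.arg(method)
  if (is.null(sf)) stop("resample_to_standard: sf not supplied", call. = FALSE)
  n_out <- n_steps * samples_per_step
  n_in <- length(truncated$ap)
  x_in <- seq_len(n_in) - 1L
  x_out <- seq(0, n_in - 1L, length.out = n_out)
  interp <- function(y) {
    if (n_in == n_out) return(y)
    if (method == "spline")
      spline(x_in, y, xout = x_out, method = "fmm")$y
    else
      approx(x_in, y, xout = x_out)$y
  }
  standardized_segment(ap = interp(truncated$ap), v = interp(truncated$v),
                       ml = interp(truncated$ml), norm = interp(truncated$norm),
                       sf = sf, samples_per_step = samples_per_step,
                       meta = meta)
}

#' One-call standardization of a calibrated bout
#'
#' Convenience wrapper: estimate the step frequency from the V axis,
#' truncate to `n_steps` steps, resample to the standardized grid.
#'
#' @inheritParams resample_to_standard
#' @param signals a [calibrated_signals()].
#' @param sf_band step-frequency search band (Hz).
#' @return a [standardized_segment()].
#' @export
standardize_bout <- function(signals, n_steps = 250, samples_per_step = 75,
                             sf_band = c(1.2, 3.0), meta = list()) {
  est <- estimate_step_frequency(signals$v, signals$fs, band = sf_band)
  tr <- truncate_to_steps(signals, est$sf, n_steps = n_steps)
  resample_to_standard(tr, sf = est$sf, n_steps = n_steps,
                       samples_per_step = samples_per_step, meta = meta)
}
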