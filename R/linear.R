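#' Movement intensity: RMS of the vector norm and the RMS ratio
#'
#' `rms_norm` is the root mean square of the gravity-free vector norm over
#' the standardized 250 steps, a proxy for overall movement intensity (and,
#' empirically, for walking speed).  `rms_ratio = rms_ml / rms_norm`
#' normalizes the mediolateral RMS by the overall intensity, attenuating
#' speed dependence; it is read as an index of lateral gait stability.  No
#' mean removal is applied beyond the 1 g already subtracted from the norm.
#'
#' @param segment a [standardized_segment()].
#' @return a list of class `intensity_result` with `rms_norm`, `rms_ml`,
#'   `rms_ratio` (all g except the dimensionless ratio).
#' @export
movement_intensity <- function(segment) {
  stopifnot(inherits(segment, "standardized_segment"))
  rms <- function(x) sqrt(mean(x * x))
  rn <- rms(segment$norm)
  rm <- rms(segment$ml)
  if (rn <= 0) stop("movement_intensity: zero-energy norm signal", call. = FALSE)
  structure(list(rms_norm = rn, rms_ml = rm, rms_ratio = rm / rn),
            class = "intensity_result")
}

# unbiased sample autocorrelation up to max_lag, normalized by lag 0
.acf_unbiased <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  r <- vapply(0:max_lag, function(k) {
    sum(x[seq_len(n - k)] * x[(k + 1L):n]) / (n - k)
  }, numeric(1))
  r / r[1L]
}

#' Step and stride regularity from the unbiased autocorrelation function
#'
#' Computes the unbiased ACF of the (mean-centred) vector norm, normalized
#' by its zero-lag value, and reads off the first and second dominant
#' periods: the step peak is the ACF maximum within 0.5--1.5 step periods,
#' the stride peak within 1.5--2.5 step periods.  On the standardized grid
#' the nominal lags are exactly 75 and 150 samples.  Peak values are the
#' regularity coefficients, between -1 and 1; Fisher's transform
#' `z = atanh(r)` (with `r` clamped to +/-(1 - 1e-12)) normalizes them for
#' group statistics.  A window whose maximum sits on a window edge has no
#' interior local maximum; the result is flagged in `step_ok` /
#' `stride_ok` rather than silently returned.
#'
#' @param segment a [standardized_segment()] (or a plain numeric signal via
#'   `signal`+`samples_per_step`).
#' @param window half-width of the peak search windows as a fraction of the
#'   nominal lag (default 0.5).
#' @return list of class `regularity_result`: `step_regularity_r`,
#'   `stride_regularity_r`, `step_regularity_z`, `stride_regularity_z`,
#'   `step_lag`, `stride_lag`, `step_ok`, `stride_ok`.
#' @export
acf_regularity <- function(segment, window = 0.5) {
  if (inherits(segment, "standardized_segment")) {
    x <- segment$norm
    sps <- segment$samples_per_step
  } else stop("acf_regularity: need a standardized_segment", call. = FALSE)
  # the unbiased estimator misbehaves at large lags; stay well below N/2
  max_lag <- min(ceiling((2 + window) * sps), 250L)
  r <- .acf_unbiased(x, max_lag)
  pick <- function(lo, hi) {
    lags <- max(1L, ceiling(lo)):min(max_lag, floor(hi))
    vals <- r[lags + 1L]
    i <- which.max(vals)           # ties break toward the smaller lag
    list(r = vals[i], lag = lags[i],
         ok = i != 1L && i != length(vals))
  }
  stp <- pick((1 - window) * sps, (1 + window) * sps)
  str <- pick((1 + window) * sps, (3 - window) * sps)
  clamp <- function(v) max(-(1 - 1e-12), min(1 - 1e-12, v))
  structure(list(step_regularity_r = stp$r,
                 stride_regularity_r = str$r,
                 step_regularity_z = atanh(clamp(stp$r)),
                 stride_regularity_z = atanh(clamp(str$r)),
                 step_lag = stp$lag, stride_lag = str$lag,
                 step_ok = stp$ok, stride_ok = str$ok),
            class = "regularity_result")
}
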