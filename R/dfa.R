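#' Stride-interval series
#'
#' Ordered stride durations (s) extracted from a foot sensor, together with
#' the sample indices of the detected gait events.  Intervals outside the
#' plausibility gate (default 0.4--2.5 s) are excluded at construction and
#' reported in `n_rejected`.
#'
#' @param intervals stride durations (s).
#' @param source_peaks 0-based sample indices of the events delimiting
#'   them, or `NULL` when imported from a bare interval file.
#' @param gate plausibility gate `c(lo, hi)` in seconds.
#' @return object of class `stride_series`.
#' @export
stride_series <- function(intervals, source_peaks = NULL,
                          gate = c(0.4, 2.5)) {
  intervals <- as.numeric(intervals)
  bad <- which(intervals < gate[1] | intervals > gate[2])
  if (length(bad)) {
    .gv_msg(sprintf("stride_series: excluding %d intervals outside [%g, %g] s (at positions %s)",
                    length(bad), gate[1], gate[2],
                    paste(utils::head(bad, 10L), collapse = ", ")))
    intervals <- intervals[-bad]
  }
  if (any(intervals <= 0)) stop("stride_series: non-positive interval", call. = FALSE)
  structure(list(intervals = intervals, n = length(intervals),
                 source_peaks = source_peaks, n_rejected = length(bad)),
            class = "stride_series")
}

#' @export
length.stride_series <- function(x) x$n

#' @export
print.stride_series <- function(x, ...) {
  cat(sprintf("<stride_series> n=%d, mean=%.3f s, sd=%.3f s\n",
              x$n, mean(x$intervals), sd(x$intervals)))
  invisible(x)
}

# strict local maxima of a numeric vector (1-based indices)
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

#' Detect strides from a foot accelerometer trace
#'
#' Peak detection on the gravity-free vector norm of the foot signal: each
#' high-prominence impact peak marks one stride, and successive peak-time
#' differences are the stride intervals.  Candidate peaks must rise at
#' least `min_prominence` above the surrounding signal; a first greedy pass
#' (0.3 s minimum separation) estimates the median stride time, and the
#' final pass enforces a separation of half that running estimate.
#' Intervals outside the plausibility gate are excluded (with a log line
#' naming their positions).
#'
#' @param foot a foot-site [accel_trace()].
#' @param bout optional [walking_bout()] restricting the span analysed
#'   (indices interpreted on the foot trace).
#' @param min_prominence minimum peak prominence (g); default 1.0.
#' @param gate interval plausibility gate (s).
#' @param min_strides minimum detected stride count; fewer is an error
#'   (DFA needs headroom over its smallest box of 16).
#' @return a [stride_series()].
#' @export
detect_strides <- function(foot, bout = NULL, min_prominence = 1.0,
                           gate = c(0.4, 2.5), min_strides = 64L) {
  stopifnot(inherits(foot, "accel_trace"))
  fs <- foot$fs
  offset <- 0L
  nrm <- vector_norm(foot)
  if (!is.null(bout)) {
    nrm <- nrm[(bout$start_idx + 1L):bout$end_idx]
    offset <- bout$start_idx
  }
  cand <- .local_maxima(nrm)
  if (length(cand)) {
    # prominence relative to the running baseline: local maxima must clear
    # the median of the signal in a +/-0.5 s window by min_prominence
    w <- as.integer(round(0.5 * fs))
    prom <- vapply(cand, function(i) {
      lo <- max(1L, i - w); hi <- min(length(nrm), i + w)
      nrm[i] - median(nrm[lo:hi])
    }, numeric(1))
    cand <- cand[prom >= min_prominence]
  }
  greedy <- function(cand, min_sep) {
    keep <- integer()
    ord <- cand[order(nrm[cand], decreasing = TRUE)]
    for (i in ord)
      if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
    sort(keep)
  }
  if (length(cand) >= 2L) {
    pk <- greedy(cand, as.integer(round(0.3 * fs)))
    med <- median(diff(pk))
    pk <- greedy(cand, max(1L, as.integer(round(0.5 * med))))
  } else pk <- cand
  if (length(pk) < min_strides + 1L)
    stop(sprintf("detect_strides: only %d strides detected (need >= %d for DFA headroom)",
                 max(0L, length(pk) - 1L), min_strides), call. = FALSE)
  stride_series(diff(pk) / fs, source_peaks = pk - 1L + offset, gate = gate)
}

#' Detrended fluctuation analysis of a stride-interval series
#'
#' DFA1: the mean-centred series is integrated (cumulative sum), partitioned
#' into non-overlapping boxes of size `n` from the start *and* from the end
#' of the series (the two coverages are averaged, so no point is wasted
#' when N is not a multiple of n), a least-squares line is removed per box,
#' and `F(n)` is the RMS residual.  The scaling exponent `alpha` is the
#' log--log slope of `F(n)` versus `n` over box sizes evenly spaced on the
#' log axis between `box_min` and `floor(N/2)`.  `alpha` is 0.5 for white
#' noise, 1.5 for its integral, 0.7--1.0 for persistent "fractal" series
#' and below 0.5 for anti-persistent ones.
#'
#' @param intervals a [stride_series()] or numeric vector (n >= 64).
#' @param box_min smallest box size (default 16).
#' @param box_max largest box size (default `floor(N/2)`).
#' @param n_boxes number of box sizes on the log grid (deduplicated after
#'   integer rounding).
#' @param coverage `"both"` (forward + backward, averaged; default) or
#'   `"forward"`.
#' @return object of class `dfa_result`: `alpha`, `box_sizes`,
#'   `fluctuations`, `fit_r2`.
#' @export
dfa <- function(intervals, box_min = 16, box_max = NULL, n_boxes = 16,
                coverage = c("both", "forward")) {
  coverage <- match.arg(coverage)
  x <- if (inherits(intervals, "stride_series")) intervals$intervals
       else as.numeric(intervals)
  N <- length(x)
  if (N < 64L) stop("dfa: need at least 64 intervals", call. = FALSE)
  if (is.null(box_max)) box_max <- floor(N / 2)
  if (box_max < box_min) stop("dfa: box_max < box_min", call. = FALSE)
  sizes <- unique(round(exp(seq(log(box_min), log(box_max),
                                length.out = n_boxes))))
  y <- cumsum(x - mean(x))
  box_rms2 <- function(seg) {
    # residual mean square after linear detrend of one box
    t <- seq_along(seg)
    f <- lm.fit(cbind(1, t), seg)
    mean(f$residuals^2)
  }
  Fn <- vapply(sizes, function(s) {
    k <- N %/% s
    idx <- seq_len(k * s)
    fwd <- matrix(y[idx], nrow = s)
    ms <- apply(fwd, 2L, box_rms2)
    if (coverage == "both") {
      bwd <- matrix(y[N + 1L - rev(idx)], nrow = s)
      ms <- c(ms, apply(bwd, 2L, box_rms2))
    }
    sqrt(mean(ms))
  }, numeric(1))
  if (any(Fn <= 0))
    stop("dfa: zero fluctuation at some box size; series degenerate", call. = FALSE)
  lx <- log(sizes); ly <- log(Fn)
  b <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  resid <- ly - (mean(ly) + b * (lx - mean(lx)))
  r2 <- 1 - sum(resid^2) / sum((ly - mean(ly))^2)
  structure(list(alpha = b, box_sizes = sizes, fluctuations = Fn,
                 fit_r2 = r2, n = N, coverage = coverage),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha=%.3f (r2=%.3f) over %d box sizes [%d..%d], N=%d\n",
              x$alpha, x$fit_r2, length(x$box_sizes),
              min(x$box_sizes), max(x$box_sizes), x$n))
  invisible(x)
}

#' Classify a DFA scaling exponent
#'
#' Persistent (fractal, high-complexity) if `0.7 <= alpha <= 1.0`;
#' anti-persistent if `alpha < 0.5`; indeterminate otherwise.
#'
#' @param alpha scaling exponent (finite scalar) or a `dfa_result`.
#' @return one of `"persistent"`, `"anti-persistent"`, `"indeterminate"`.
#' @export
classify_persistence <- function(alpha) {
  if (inherits(alpha, "dfa_result")) alpha <- alpha$alpha
  if (!is.finite(alpha)) stop("classify_persistence: alpha not finite", call. = FALSE)
  if (alpha >= 0.7 && alpha <= 1.0) "persistent"
  else if (alpha < 0.5) "anti-persistent"
  else "indeterminate"
}

#' Read / write stride-interval series as two-column delimited text
#'
#' Columns `index`, `interval_s`; lets DFA run on externally produced
#' gait-event series.
#'
#' @param x a [stride_series()].
#' @param path file path.
#' @return `write_stride_series` returns `path` invisibly;
#'   `read_stride_series` returns a [stride_series()].
#' @export
write_stride_series <- function(x, path) {
  stopifnot(inherits(x, "stride_series"))
  write.table(data.frame(index = seq_len(x$n) - 1L,
                         interval_s = format(x$intervals, digits = 17)),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stride_series
#' @export
read_stride_series <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!"interval_s" %in% names(df))
    stop("read_stride_series: missing interval_s column", call. = FALSE)
  stride_series(as.numeric(df$interval_s))
}
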