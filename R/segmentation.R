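#' Walking-bout container
#'
#' A half-open, 0-based sample range `[start_idx, end_idx)` into a source
#' [accel_trace()], labelled `segment1`, `segment2`, ... in temporal order.
#'
#' @param source an [accel_trace()].
#' @param start_idx,end_idx half-open 0-based sample indices.
#' @param label bout label.
#' @return an object of class `walking_bout`.
#' @export
walking_bout <- function(source, start_idx, end_idx, label = "segment1") {
  stopifnot(inherits(source, "accel_trace"))
  n <- length(source$ax)
  start_idx <- as.integer(start_idx); end_idx <- as.integer(end_idx)
  if (start_idx < 0L || start_idx >= end_idx || end_idx > n)
    stop("walking_bout: need 0 <= start_idx < end_idx <= length(source)",
         call. = FALSE)
  structure(list(source = source, start_idx = start_idx, end_idx = end_idx,
                 label = label),
            class = "walking_bout")
}

#' @export
length.walking_bout <- function(x) x$end_idx - x$start_idx

#' @export
print.walking_bout <- function(x, ...) {
  cat(sprintf("<walking_bout> %s [%d, %d) = %.1f s @ %g Hz\n", x$label,
              x$start_idx, x$end_idx,
              (x$end_idx - x$start_idx) / x$source$fs, x$source$fs))
  invisible(x)
}

.bout_channels <- function(bout) {
  idx <- (bout$start_idx + 1L):bout$end_idx
  list(ax = bout$source$ax[idx], ay = bout$source$ay[idx],
       az = bout$source$az[idx], fs = bout$source$fs)
}

#' Segmentation configuration
#'
#' Controls for [detect_walking_bouts()].  Explicit ranges, when given,
#' bypass the automatic detector entirely: this is the manual-override path
#' replacing by-eye segmentation of the raw record.
#'
#' @param min_bout_s minimum bout duration (s).
#' @param activity_threshold moving-window variance of the gravity-free
#'   vector norm (g^2) above which a window counts as active.
#' @param sf_band frequency band (Hz) the dominant frequency of an active
#'   span must fall in to qualify as walking.
#' @param window_s moving-variance window length (s).
#' @param merge_gap_s inactive gaps shorter than this are bridged.
#' @param explicit_ranges optional list of `c(start_idx, end_idx)` half-open
#'   0-based ranges; when non-NULL these are returned verbatim as bouts.
#' @return a list of class `seg_config`.
#' @export
seg_config <- function(min_bout_s = 60, activity_threshold = 1e-3,
                       sf_band = c(1.2, 3.0), window_s = 2,
                       merge_gap_s = 2, explicit_ranges = NULL) {
  structure(list(min_bout_s = min_bout_s,
                 activity_threshold = activity_threshold,
                 sf_band = sf_band, window_s = window_s,
                 merge_gap_s = merge_gap_s,
                 explicit_ranges = explicit_ranges),
            class = "seg_config")
}

# centered moving variance via running sums; returns a vector of length(x)
.moving_var <- function(x, w) {
  w <- max(3L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  k <- rep(1 / w, w)
  mu <- stats::filter(x, k, sides = 2)
  mu2 <- stats::filter(x * x, k, sides = 2)
  v <- as.numeric(mu2 - mu * mu)
  # pad the half-window edges with the nearest interior value
  h <- (w - 1L) %/% 2L
  n <- length(x)
  v[seq_len(h)] <- v[h + 1L]
  v[(n - h + 1L):n] <- v[n - h]
  pmax(v, 0)
}

#' Detect steady-walking bouts in a trace
#'
#' Automatic segmentation: samples whose moving-window variance of the
#' gravity-free vector norm exceeds `cfg$activity_threshold` are marked
#' active; contiguous active runs (gaps below `cfg$merge_gap_s` bridged) that
#' last at least `cfg$min_bout_s` and whose dominant frequency falls inside
#' `cfg$sf_band` become bouts.  Explicit ranges in the config always win.
#' Discarded spans are reported through `attr(, "discarded")` and, when
#' `options(gaitvar.verbose = TRUE)`, logged with sample indices.
#'
#' @param trace an [accel_trace()].
#' @param cfg a [seg_config()].
#' @return a list of [walking_bout()]s (possibly empty), ordered and
#'   disjoint.
#' @export
detect_walking_bouts <- function(trace, cfg = seg_config()) {
  stopifnot(inherits(trace, "accel_trace"))
  fs <- trace$fs
  if (!is.null(cfg$explicit_ranges)) {
    bouts <- lapply(seq_along(cfg$explicit_ranges), function(i) {
      r <- cfg$explicit_ranges[[i]]
      walking_bout(trace, r[1], r[2], label = paste0("segment", i))
    })
    return(bouts)
  }
  nrm <- sqrt(trace$ax^2 + trace$ay^2 + trace$az^2) - 1
  v <- .moving_var(nrm, round(cfg$window_s * fs))
  active <- v > cfg$activity_threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # bridge short inactive gaps between active runs
  gap <- round(cfg$merge_gap_s * fs)
  act <- active
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] && r$lengths[k] <= gap &&
        k > 1L && k < length(r$lengths))
      act[starts[k]:ends[k]] <- TRUE
  }
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_n <- round(cfg$min_bout_s * fs)
  bouts <- list()
  discarded <- list()
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    s0 <- starts[k] - 1L; e0 <- ends[k]    # to 0-based half-open
    if (r$lengths[k] < min_n) {
      discarded <- c(discarded, list(c(s0, e0)))
      .gv_msg(sprintf("discarding short active span [%d, %d)", s0, e0))
      next
    }
    sfq <- tryCatch(
      estimate_step_frequency(nrm[(s0 + 1L):e0], fs, band = cfg$sf_band),
      error = function(e) NULL)
    if (is.null(sfq)) {
      discarded <- c(discarded, list(c(s0, e0)))
      .gv_msg(sprintf("discarding aperiodic active span [%d, %d)", s0, e0))
      next
    }
    bouts <- c(bouts, list(walking_bout(trace, s0, e0,
                                        label = paste0("segment", length(bouts) + 1L))))
  }
  attr(bouts, "discarded") <- discarded
  bouts
}
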