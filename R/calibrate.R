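#' Calibrated (tilt-corrected) axis signals
#'
#' Output of [calibrate_tilt()]: anteroposterior (`ap`), vertical (`v`) and
#' mediolateral (`ml`) accelerations in a horizontal--vertical frame, plus
#' the gravity-free vector norm.  `v` retains its +1 g static component;
#' `norm` has 1 g subtracted and is orientation-independent by construction.
#'
#' @param ap,v,ml,norm equal-length numeric vectors (g).
#' @param fs sampling rate (Hz).
#' @return an object of class `calibrated_signals`.
#' @export
calibrated_signals <- function(ap, v, ml, norm, fs) {
  n <- length(ap)
  if (length(v) != n || length(ml) != n || length(norm) != n)
    stop("calibrated_signals: all four signals must have equal length",
         call. = FALSE)
  structure(list(ap = ap, v = v, ml = ml, norm = norm, fs = fs),
            class = "calibrated_signals")
}

#' @export
length.calibrated_signals <- function(x) length(x$ap)

#' Gravity-free vector norm of a 3-axis acceleration signal
#'
#' `sqrt(ax^2 + ay^2 + az^2) - 1` in g units.  The norm is invariant under
#' any rotation of the sensor frame, which makes metrics computed from it
#' robust to mounting orientation; subtracting 1 g removes the static
#' component of Earth gravity.
#'
#' @param x an [accel_trace()], [walking_bout()], [calibrated_signals()],
#'   or a 3-column numeric matrix.
#' @return numeric vector (g).
#' @export
vector_norm <- function(x) {
  if (inherits(x, "accel_trace"))
    return(sqrt(x$ax^2 + x$ay^2 + x$az^2) - 1)
  if (inherits(x, "walking_bout")) {
    ch <- .bout_channels(x)
    return(sqrt(ch$ax^2 + ch$ay^2 + ch$az^2) - 1)
  }
  if (inherits(x, "calibrated_signals"))
    return(sqrt(x$ap^2 + x$v^2 + x$ml^2) - 1)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("vector_norm: need 3 channels", call. = FALSE)
  sqrt(rowSums(x * x)) - 1
}

#' Tilt calibration of a trunk acceleration bout
#'
#' Rotates the per-bout mean acceleration (the gravity estimate) onto the
#' vertical axis with two successive planar rotations: first in the
#' sagittal (AP--V) plane, then in the frontal (ML--V) plane.  After
#' calibration the AP and ML signals have zero mean over the bout and the V
#' signal carries the full static gravity component (mean approximately
#' 1 g).  A static, tilted sensor therefore maps to `v == 1`, `ap == ml == 0`
#' exactly, and calibrating twice equals calibrating once.
#'
#' The raw-channel-to-anatomy assignment is declared via `axis_map` (device
#' mounting varies and is not auto-inferred).  With `axis_map = NULL` the
#' channel with the largest absolute mean is assigned to V (AP and ML keep
#' file order) and a warning is issued.
#'
#' @param bout a [walking_bout()] of at least 10 s (or an [accel_trace()],
#'   taken whole).
#' @param axis_map named character vector `c(ap=, v=, ml=)` over
#'   `"ax","ay","az"`, or `NULL` for guess-V-only.
#' @return a [calibrated_signals()].
#' @export
calibrate_tilt <- function(bout, axis_map = c(ap = "ax", v = "ay", ml = "az")) {
  if (inherits(bout, "calibrated_signals")) {
    bout <- accel_trace(bout$ap, bout$v, bout$ml, fs = bout$fs)
    axis_map <- c(ap = "ax", v = "ay", ml = "az")
  }
  if (inherits(bout, "accel_trace"))
    bout <- walking_bout(bout, 0L, length(bout$ax))
  stopifnot(inherits(bout, "walking_bout"))
  ch <- .bout_channels(bout)
  if ((bout$end_idx - bout$start_idx) / ch$fs < 10)
    stop("calibrate_tilt: bout shorter than 10 s", call. = FALSE)
  if (is.null(axis_map)) {
    mu <- abs(c(ax = mean(ch$ax), ay = mean(ch$ay), az = mean(ch$az)))
    vch <- names(which.max(mu))
    rest <- setdiff(c("ax", "ay", "az"), vch)
    axis_map <- c(ap = rest[1], v = vch, ml = rest[2])
    warning("calibrate_tilt: axis_map not given; assigned V to channel '",
            vch, "' by largest mean", call. = FALSE)
  }
  ap0 <- ch[[axis_map[["ap"]]]]
  v0  <- ch[[axis_map[["v"]]]]
  ml0 <- ch[[axis_map[["ml"]]]]
  ma <- mean(ap0); mv <- mean(v0); mm <- mean(ml0)
  g0 <- sqrt(ma^2 + mv^2 + mm^2)
  if (g0 < 0.5 || g0 > 1.5)
    stop(sprintf(paste0("calibrate_tilt: mean acceleration magnitude %.3f g ",
                        "outside [0.5, 1.5]; sensor is not near-static ",
                        "gravity on average"), g0), call. = FALSE)
  # sagittal rotation: zero the AP mean
  th1 <- atan2(ma, mv)
  c1 <- cos(th1); s1 <- sin(th1)
  ap1 <- ap0 * c1 - v0 * s1
  v1  <- ap0 * s1 + v0 * c1
  # frontal rotation: zero the ML mean
  th2 <- atan2(mm, sqrt(ma^2 + mv^2))
  c2 <- cos(th2); s2 <- sin(th2)
  ml1 <- ml0 * c2 - v1 * s2
  v2  <- ml0 * s2 + v1 * c2
  calibrated_signals(ap = ap1, v = v2, ml = ml1,
                     norm = sqrt(ap0^2 + v0^2 + ml0^2) - 1, fs = ch$fs)
}
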