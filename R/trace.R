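#' Triaxial acceleration trace
#'
#' An `accel_trace` is a uniformly sampled 3-axis acceleration record in g
#' units: the raw material of every analysis in this package.  Channels are
#' stored as recorded by the device (`ax`, `ay`, `az`); anatomical meaning
#' (anteroposterior / vertical / mediolateral) is only assigned later, by
#' [calibrate_tilt()] together with an axis mapping.
#'
#' @param ax,ay,az numeric vectors of equal length (acceleration, g).
#' @param fs sampling rate in Hz (positive scalar).
#' @param site sensor placement, `"lumbar"` or `"foot"`.
#' @param t0 start time of the record in seconds (sample `i` is at
#'   `t0 + (i - 1) / fs`).
#' @return an object of class `accel_trace`.
#' @seealso [read_trace()], [detect_walking_bouts()]
#' @export
accel_trace <- function(ax, ay, az, fs, site = c("lumbar", "foot"), t0 = 0) {
  site <- match.arg(site)
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(ax)
  if (length(ay) != n || length(az) != n)
    stop("accel_trace: channels must have equal length", call. = FALSE)
  if (n < 2L) stop("accel_trace: need at least 2 samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("accel_trace: fs must be a positive scalar", call. = FALSE)
  structure(
    list(ax = ax, ay = ay, az = az, fs = as.numeric(fs),
         site = site, t0 = as.numeric(t0)),
    class = "accel_trace")
}

#' @export
length.accel_trace <- function(x) length(x$ax)

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> site=%s fs=%g Hz n=%d (%.1f s)\n",
              x$site, x$fs, length(x$ax), length(x$ax) / x$fs))
  invisible(x)
}

#' Default column schema for delimited trace files
#'
#' Describes how a delimited text file maps onto an [accel_trace()]: which
#' columns hold time and the three acceleration channels, the acceleration
#' units, and optional overrides.  Axis-to-anatomy mapping is deliberately
#' *not* auto-inferred from data (device mounting varies); it is declared
#' here and consumed by [calibrate_tilt()].
#'
#' @param time name of the time column, or `NA` for an implicit index
#'   (requires `fs`).
#' @param ax,ay,az names of the acceleration columns.
#' @param units `"g"` or `"m/s2"`; m/s^2 inputs are divided by 9.81.
#' @param fs optional sampling-rate override (Hz); mandatory when `time`
#'   is `NA`.
#' @param site sensor placement tag.
#' @param axis_map named character vector mapping anatomical axes to raw
#'   channels, e.g. `c(ap = "ax", v = "ay", ml = "az")` (the default).
#' @param sep field separator passed to the reader.
#' @return a list of class `trace_schema`.
#' @export
trace_schema <- function(time = "t", ax = "ax", ay = "ay", az = "az",
                         units = c("g", "m/s2"), fs = NULL,
                         site = c("lumbar", "foot"),
                         axis_map = c(ap = "ax", v = "ay", ml = "az"),
                         sep = ",") {
  units <- match.arg(units)
  site <- match.arg(site)
  stopifnot(all(sort(names(axis_map)) == c("ap", "ml", "v")),
            all(axis_map %in% c("ax", "ay", "az")))
  structure(list(time = time, ax = ax, ay = ay, az = az, units = units,
                 fs = fs, site = site, axis_map = axis_map, sep = sep),
            class = "trace_schema")
}

#' Read a delimited accelerometer file
#'
#' Reads a header-bearing delimited text file into an [accel_trace()].  The
#' sampling rate is inferred from the median time step unless the schema
#' overrides it; sampling jitter beyond 1% of the median step is rejected as
#' non-uniform.
#'
#' @param path file path.
#' @param schema a [trace_schema()].
#' @return an [accel_trace()].
#' @export
read_trace <- function(path, schema = trace_schema()) {
  if (!file.exists(path)) stop("read_trace: no such file: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = schema$sep,
                   check.names = FALSE, comment.char = "#")
  need <- c(schema$ax, schema$ay, schema$az)
  if (!is.na(schema$time)) need <- c(schema$time, need)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_trace: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.na(schema$time)) {
    tt <- as.numeric(df[[schema$time]])
    dt <- diff(tt)
    if (any(dt <= 0)) stop("read_trace: non-monotone time column", call. = FALSE)
    med <- median(dt)
    if (any(abs(dt - med) > 0.01 * med))
      stop("read_trace: non-uniform sampling (jitter exceeds 1% of the median step)",
           call. = FALSE)
    fs <- if (!is.null(schema$fs)) schema$fs else 1 / med
    t0 <- tt[1L]
  } else {
    if (is.null(schema$fs))
      stop("read_trace: schema without a time column must supply fs", call. = FALSE)
    fs <- schema$fs
    t0 <- 0
  }
  scl <- if (schema$units == "m/s2") 1 / GV_GRAVITY else 1
  accel_trace(df[[schema$ax]] * scl, df[[schema$ay]] * scl,
              df[[schema$az]] * scl, fs = fs, site = schema$site, t0 = t0)
}

#' Write an acceleration trace as delimited text
#'
#' Inverse of [read_trace()]: columns `t, ax, ay, az`, comma-separated, in g.
#' Values are written with full precision so a write/read round trip
#' reproduces the channels bit-exactly.
#'
#' @param trace an [accel_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  n <- length(trace$ax)
  tt <- trace$t0 + (seq_len(n) - 1) / trace$fs
  df <- data.frame(t = format(tt, digits = 17),
                   ax = format(trace$ax, digits = 17),
                   ay = format(trace$ay, digits = 17),
                   az = format(trace$az, digits = 17))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
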