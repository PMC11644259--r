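#' Takens delay embedding of a scalar signal
#'
#' Builds the attractor matrix whose row `i` is
#' `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`; the number of rows is
#' `length(x) - (m - 1) * tau`.
#'
#' Defaults (`m = 6`, `tau = 15` samples = 0.1 stride on the standardized
#' grid) were chosen once by the usual average-mutual-information /
#' false-nearest-neighbour heuristics run on synthetic gait and are recorded
#' in every downstream result; both are plain arguments.
#'
#' @param x numeric signal.
#' @param m embedding dimension (>= 2).
#' @param tau embedding delay in samples (>= 1).
#' @return numeric matrix with `m` columns.
#' @export
embed_delay <- function(x, m = 6, tau = 15) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 2L || tau < 1L)
    stop("embed_delay: need m >= 2 and tau >= 1", call. = FALSE)
  n <- length(x) - (m - 1L) * tau
  if (n < 1L)
    stop("embed_delay: signal too short for (m - 1) * tau delays", call. = FALSE)
  idx <- seq_len(n)
  out <- matrix(0, n, m)
  for (k in seq_len(m)) out[, k] <- x[idx + (k - 1L) * tau]
  out
}

#' Mean logarithmic divergence curve (Rosenstein's algorithm)
#'
#' For every attractor point the Euclidean nearest neighbour outside a
#' Theiler exclusion window is located, and the pair's separation is
#' tracked forward in time: the curve is the mean over all pairs of
#' `ln ||x_{j+t} - x_{nn(j)+t}||`.  Pairs whose track runs off the end of
#' the data are dropped from the mean at that `t` (the time span is not
#' truncated globally).  Exact zero distances are replaced by the smallest
#' positive distance observed on the curve; the count of substitutions and
#' the floor used are reported.  Nearest-neighbour ties break toward the
#' smaller index, so identical inputs give bit-identical curves.
#'
#' @param attractor matrix from [embed_delay()].
#' @param samples_per_stride samples per time unit on the curve's time
#'   axis; 150 for standardized gait segments (so slopes come out in
#'   nats/stride).  For non-gait signals pass samples-per-second to get
#'   nats/s.
#' @param t_max_strides time horizon of the curve, in the same unit.
#' @param theiler_w Theiler exclusion half-window in samples; default one
#'   stride (150) to keep serially correlated points out of the
#'   neighbour search.
#' @return object of class `divergence_curve`: `t` (time units), `d`
#'   (mean log divergence, nats), `n_pairs`, `n_zero_replaced`,
#'   `dist_floor`.
#' @export
rosenstein_divergence <- function(attractor, samples_per_stride = 150,
                                  t_max_strides = 12.5, theiler_w = 150) {
  stopifnot(is.matrix(attractor))
  n <- nrow(attractor)
  t_max <- as.integer(round(t_max_strides * samples_per_stride))
  if (n <= t_max + theiler_w)
    stop("rosenstein_divergence: attractor too short for the requested horizon",
         call. = FALSE)
  res <- .gv_rosenstein_cpp(attractor, as.integer(theiler_w), t_max)
  if (res$n_pairs[1L] < 100L)
    stop("rosenstein_divergence: fewer than 100 valid neighbour pairs; attractor degenerate",
         call. = FALSE)
  if (res$n_zero_replaced > 0L)
    .gv_msg(sprintf("rosenstein_divergence: %d zero distances floored at %.3g",
                    res$n_zero_replaced, res$dist_floor))
  structure(list(t = (0:t_max) / samples_per_stride, d = res$d,
                 n_pairs = res$n_pairs,
                 n_zero_replaced = res$n_zero_replaced,
                 dist_floor = res$dist_floor),
            class = "divergence_curve")
}

#' @export
print.divergence_curve <- function(x, ...) {
  cat(sprintf("<divergence_curve> %d points over %.2f strides, %d pairs at t=0\n",
              length(x$t), max(x$t), x$n_pairs[1L]))
  invisible(x)
}

#' Write a divergence curve as two-column delimited text
#'
#' @param curve a `divergence_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_divergence_curve <- function(curve, path) {
  write.table(data.frame(t_strides = curve$t, mean_log_divergence = curve$d),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit short- and long-term divergence exponents
#'
#' Ordinary least-squares line fits of the divergence curve restricted to
#' two windows (endpoints inclusive): the short-term slope over 0--0.5
#' strides is the local dynamic stability (LDS; larger = locally less
#' stable), the long-term slope over 5--12 strides is the attractor
#' complexity index (ACI; tracks the correlation structure of successive
#' strides).  Both are in nats/stride.
#'
#' @param curve a `divergence_curve`.
#' @param lds_window,aci_window fit windows in strides.
#' @return list of class `divergence_exponents`: `lds`, `aci`,
#'   `lds_r2`, `aci_r2`, the windows used.
#' @export
fit_exponents <- function(curve, lds_window = c(0, 0.5),
                          aci_window = c(5, 12)) {
  stopifnot(inherits(curve, "divergence_curve"))
  if (max(curve$t) < max(aci_window, lds_window))
    stop("fit_exponents: fit window extends beyond the curve span", call. = FALSE)
  fit1 <- function(win) {
    eps <- 1e-9
    sel <- which(curve$t >= win[1] - eps & curve$t <= win[2] + eps &
                   is.finite(curve$d))
    if (length(sel) < 2L)
      stop("fit_exponents: fewer than 2 finite points in fit window", call. = FALSE)
    tt <- curve$t[sel]; dd <- curve$d[sel]
    b <- sum((tt - mean(tt)) * (dd - mean(dd))) / sum((tt - mean(tt))^2)
    resid <- dd - (mean(dd) + b * (tt - mean(tt)))
    tss <- sum((dd - mean(dd))^2)
    r2 <- if (tss > 0) 1 - sum(resid^2) / tss else 1
    c(slope = b, r2 = r2)
  }
  l <- fit1(lds_window); a <- fit1(aci_window)
  structure(list(lds = unname(l["slope"]), aci = unname(a["slope"]),
                 lds_r2 = unname(l["r2"]), aci_r2 = unname(a["r2"]),
                 lds_window = lds_window, aci_window = aci_window),
            class = "divergence_exponents")
}

#' LDS and ACI for a standardized gait segment
#'
#' Runs embedding, Rosenstein divergence and exponent fitting per axis and
#' returns the axis/exponent combinations reported in trunk-accelerometry
#' work: LDS along ML (frontal-plane local stability) and ACI along AP, V
#' and the vector norm (long-range complexity).  Other combinations are
#' available by passing `axes`.
#'
#' @param segment a [standardized_segment()].
#' @param m,tau embedding dimension and delay (samples).
#' @param theiler_w Theiler window (samples).
#' @param t_max_strides divergence-curve horizon (strides).
#' @param lds_window,aci_window fit windows (strides).
#' @param axes character vector of axes to process, subset of
#'   `c("ap", "v", "ml", "norm")`.
#' @param keep_curves if TRUE, attach the divergence curves.
#' @return list of class `lds_aci_result` with named scalars `lds_ml`,
#'   `aci_ap`, `aci_v`, `aci_n` (those whose axes were computed), the full
#'   per-axis exponent fits in `$fits`, and the embedding parameters.
#' @export
compute_lds_aci <- function(segment, m = 6, tau = 15, theiler_w = 150,
                            t_max_strides = 12.5,
                            lds_window = c(0, 0.5), aci_window = c(5, 12),
                            axes = c("ml", "ap", "v", "norm"),
                            keep_curves = FALSE) {
  stopifnot(inherits(segment, "standardized_segment"))
  axes <- match.arg(axes, c("ap", "v", "ml", "norm"), several.ok = TRUE)
  sps <- segment$samples_per_stride
  fits <- list(); curves <- list()
  for (ax in axes) {
    att <- embed_delay(segment[[ax]], m = m, tau = tau)
    cur <- rosenstein_divergence(att, samples_per_stride = sps,
                                 t_max_strides = t_max_strides,
                                 theiler_w = theiler_w)
    fits[[ax]] <- fit_exponents(cur, lds_window = lds_window,
                                aci_window = aci_window)
    if (keep_curves) curves[[ax]] <- cur
  }
  out <- list(fits = fits,
              params = list(m = m, tau = tau, theiler_w = theiler_w,
                            t_max_strides = t_max_strides,
                            lds_window = lds_window, aci_window = aci_window))
  if ("ml" %in% axes) out$lds_ml <- fits$ml$lds
  if ("ap" %in% axes) out$aci_ap <- fits$ap$aci
  if ("v" %in% axes) out$aci_v <- fits$v$aci
  if ("norm" %in% axes) out$aci_n <- fits$norm$aci
  if (keep_curves) out$curves <- curves
  structure(out, class = "lds_aci_result")
}
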