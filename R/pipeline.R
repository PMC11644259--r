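#' Analysis configuration
#'
#' Bundles the per-module settings for the end-to-end pipeline.  Everything
#' has the package default; any field can be overridden.  `metrics` selects
#' which families are computed (`"intensity"`, `"regularity"`,
#' `"nonlinear"`); dropping `"nonlinear"` makes runs orders of magnitude
#' faster when only linear metrics are needed.
#'
#' @param seg a [seg_config()].
#' @param axis_map raw-channel-to-anatomy map for [calibrate_tilt()].
#' @param n_steps,samples_per_step standardization geometry.
#' @param sf_band step-frequency search band (Hz).
#' @param m,tau,theiler_w embedding parameters for [compute_lds_aci()].
#' @param metrics metric families to compute.
#' @param seed global seed recorded in outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(seg = seg_config(),
                       axis_map = c(ap = "ax", v = "ay", ml = "az"),
                       n_steps = 250, samples_per_step = 75,
                       sf_band = c(1.2, 3.0),
                       m = 6, tau = 15, theiler_w = 150,
                       metrics = c("intensity", "regularity", "nonlinear"),
                       seed = 1L) {
  structure(list(seg = seg, axis_map = axis_map, n_steps = n_steps,
                 samples_per_step = samples_per_step, sf_band = sf_band,
                 m = m, tau = tau, theiler_w = theiler_w,
                 metrics = metrics, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full metric pipeline on one calibrated bout
#'
#' Calibration -> step-frequency estimation -> truncation to `n_steps`
#' steps -> resampling to the standardized grid -> all requested metric
#' families.  Returns a named list of scalar metrics.
#'
#' @param bout a [walking_bout()] (lumbar site).
#' @param cfg a [run_config()].
#' @return named list: `sf`, and per requested family `rms_norm`,
#'   `rms_ratio`, `step_regularity_z`, `stride_regularity_z`, `lds_ml`,
#'   `aci_ap`, `aci_v`, `aci_n`.
#' @export
analyze_bout <- function(bout, cfg = run_config()) {
  cal <- calibrate_tilt(bout, axis_map = cfg$axis_map)
  est <- estimate_step_frequency(cal$v, cal$fs, band = cfg$sf_band)
  tr <- truncate_to_steps(cal, est$sf, n_steps = cfg$n_steps)
  seg <- resample_to_standard(tr, sf = est$sf, n_steps = cfg$n_steps,
                              samples_per_step = cfg$samples_per_step)
  out <- list(sf = est$sf)
  if ("intensity" %in% cfg$metrics) {
    mi <- movement_intensity(seg)
    out$rms_norm <- mi$rms_norm
    out$rms_ratio <- mi$rms_ratio
  }
  if ("regularity" %in% cfg$metrics) {
    rg <- acf_regularity(seg)
    out$step_regularity_z <- rg$step_regularity_z
    out$stride_regularity_z <- rg$stride_regularity_z
  }
  if ("nonlinear" %in% cfg$metrics) {
    nl <- compute_lds_aci(seg, m = cfg$m, tau = cfg$tau,
                          theiler_w = cfg$theiler_w)
    out$lds_ml <- nl$lds_ml
    out$aci_ap <- nl$aci_ap
    out$aci_v <- nl$aci_v
    out$aci_n <- nl$aci_n
  }
  out
}

#' Analyze a raw lumbar trace end to end
#'
#' Detects walking bouts and runs [analyze_bout()] on each; bouts too short
#' to yield `n_steps` steps are skipped with a log line.
#'
#' @param trace a lumbar [accel_trace()].
#' @param cfg a [run_config()].
#' @param meta named list of labels merged into each output row.
#' @return tidy metric data.frame (see [metric_record()]); zero rows if no
#'   usable bout.
#' @export
analyze_trace <- function(trace, cfg = run_config(), meta = list()) {
  bouts <- detect_walking_bouts(trace, cfg$seg)
  rows <- list()
  for (b in bouts) {
    res <- tryCatch(analyze_bout(b, cfg), error = function(e) {
      .gv_msg(sprintf("analyze_trace: %s skipped: %s", b$label,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    rows <- c(rows, list(metric_record(
      participant = meta$participant %||% "p1",
      group = meta$group %||% "older",
      condition = meta$condition %||% "normal",
      segment = b$label, metrics = res)))
  }
  if (!length(rows))
    return(data.frame(participant = character(), group = character(),
                      condition = character(), segment = character(),
                      metric = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
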