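#' Build a tidy per-segment metric table
#'
#' One row per participant x condition x segment x metric, the hand-off
#' boundary to any downstream modelling package.  Missing metrics are
#' allowed (rows simply absent) but can be audited with
#' [aggregate_segments()]'s flags.
#'
#' @param participant,group,condition,segment vectors (recycled to equal
#'   length) of labels; `group` in `{older, young}`, `condition` in
#'   `{normal, metronome}`.
#' @param metrics named list (or single-row data.frame) of metric values.
#' @return data.frame with columns `participant`, `group`, `condition`,
#'   `segment`, `metric`, `value`.
#' @export
metric_record <- function(participant, group, condition, segment, metrics) {
  metrics <- unlist(metrics)
  data.frame(participant = participant, group = group,
             condition = condition, segment = segment,
             metric = names(metrics), value = as.numeric(metrics),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate the two walking segments of each condition
#'
#' Averages metric values over segments within participant x condition x
#' metric.  Participants with a single available segment keep that
#' segment's value and are flagged (`n_segments` column).
#'
#' @param records tidy metric table (see [metric_record()]).
#' @param outlier_sd if non-NULL, values more than this many SDs from
#'   their metric x group x condition mean are removed before aggregation
#'   (off by default); removals are logged.
#' @return data.frame with one row per participant x condition x metric:
#'   columns `participant`, `group`, `condition`, `metric`, `value`,
#'   `n_segments`.
#' @export
aggregate_segments <- function(records, outlier_sd = NULL) {
  stopifnot(all(c("participant", "group", "condition", "segment",
                  "metric", "value") %in% names(records)))
  if (!is.null(outlier_sd)) {
    grp <- interaction(records$metric, records$group, records$condition,
                       drop = TRUE)
    mu <- ave(records$value, grp)
    sdv <- ave(records$value, grp, FUN = sd)
    bad <- !is.na(sdv) & sdv > 0 & abs(records$value - mu) > outlier_sd * sdv
    if (any(bad)) {
      .gv_msg(sprintf("aggregate_segments: removing %d outlier rows (> %g SD)",
                      sum(bad), outlier_sd))
      records <- records[!bad, , drop = FALSE]
    }
  }
  key <- interaction(records$participant, records$condition, records$metric,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(df) {
    data.frame(participant = df$participant[1L], group = df$group[1L],
               condition = df$condition[1L], metric = df$metric[1L],
               value = mean(df$value), n_segments = nrow(df),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$participant, agg$condition, agg$metric), , drop = FALSE]
}

#' Hedges' g with a bias-corrected bootstrap confidence interval
#'
#' Standardized mean difference `d = (mean_a - mean_b) / s_pooled` (pooled
#' SD with n-1 weighting) multiplied by the small-sample correction
#' `J = 1 - 3 / (4 (n_a + n_b) - 9)`.  The confidence interval is a
#' bias-corrected percentile bootstrap (default 5,000 resamples, fixed
#' seed, 99% level).
#'
#' @param a,b numeric samples (each n >= 2).
#' @param conf confidence level (default 0.99).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `effect_size_result`: `g`, `ci_low`, `ci_high`,
#'   `n1`, `n2`, `mean1`, `mean2`, `sd1`, `sd2`.
#' @export
hedges_g <- function(a, b, conf = 0.99, n_boot = 5000, seed = 20240101) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L)
    stop("hedges_g: need at least 2 observations per group", call. = FALSE)
  g_of <- function(x, y) {
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    if (sp2 <= 0) stop("hedges_g: zero pooled SD", call. = FALSE)
    J <- 1 - 3 / (4 * (length(x) + length(y)) - 9)
    J * (mean(x) - mean(y)) / sqrt(sp2)
  }
  g <- g_of(a, b)
  boots <- .with_seed(seed, vapply(seq_len(n_boot), function(i) {
    xa <- a[sample.int(n1, n1, replace = TRUE)]
    xb <- b[sample.int(n2, n2, replace = TRUE)]
    tryCatch(g_of(xa, xb), error = function(e) NA_real_)
  }, numeric(1)))
  boots <- boots[is.finite(boots)]
  # bias correction: shift the percentile points by the bootstrap median bias
  z0 <- qnorm(mean(boots < g))
  alpha <- (1 - conf) / 2
  plo <- pnorm(2 * z0 + qnorm(alpha))
  phi <- pnorm(2 * z0 + qnorm(1 - alpha))
  ci <- unname(quantile(boots, c(plo, phi), type = 7))
  structure(list(g = g, ci_low = ci[1L], ci_high = ci[2L],
                 n1 = n1, n2 = n2,
                 mean1 = mean(a), mean2 = mean(b),
                 sd1 = sd(a), sd2 = sd(b), conf = conf),
            class = "effect_size_result")
}

#' Hedges' g from summary statistics
#'
#' Same point estimate as [hedges_g()] but computed from printed group
#' means, SDs and sizes (no CI).  Useful for checking published tables.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return Hedges' g (numeric scalar).
#' @export
hedges_g_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp <= 0) stop("hedges_g_summary: zero pooled SD", call. = FALSE)
  (1 - 3 / (4 * (n1 + n2) - 9)) * (mean1 - mean2) / sp
}

#' Relative change between two condition means
#'
#' `100 * (to - from) / from`, in percent.
#'
#' @param from baseline (e.g. normal-walking) mean; must be non-zero.
#' @param to comparison (e.g. metronome-walking) mean.
#' @return percent change (numeric scalar).
#' @export
relative_change <- function(from, to) {
  if (from == 0) stop("relative_change: zero baseline", call. = FALSE)
  100 * (to - from) / from
}

#' Cohort descriptive table with effect sizes
#'
#' Per metric x condition: group sizes, means and SDs, plus Hedges' g
#' (group `"older"` minus group `"young"`) with its bootstrap CI when both
#' groups are present.  Emitted as a tidy data.frame; write it with
#' [write.table()] for a delimited hand-off file.
#'
#' @param aggregated output of [aggregate_segments()].
#' @param metrics metric names to include (default: all present).
#' @param conf,n_boot,seed passed to [hedges_g()].
#' @return data.frame, one row per metric x condition.
#' @export
cohort_table <- function(aggregated, metrics = NULL, conf = 0.99,
                         n_boot = 5000, seed = 20240101) {
  if (is.null(metrics)) metrics <- sort(unique(aggregated$metric))
  rows <- list()
  for (cond in sort(unique(aggregated$condition))) {
    for (m in metrics) {
      sub <- aggregated[aggregated$metric == m & aggregated$condition == cond, ]
      o <- sub$value[sub$group == "older"]
      y <- sub$value[sub$group == "young"]
      row <- data.frame(metric = m, condition = cond,
                        n_older = length(o), n_young = length(y),
                        mean_older = if (length(o)) mean(o) else NA_real_,
                        sd_older = if (length(o) > 1) sd(o) else NA_real_,
                        mean_young = if (length(y)) mean(y) else NA_real_,
                        sd_young = if (length(y) > 1) sd(y) else NA_real_,
                        g = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE)
      if (length(o) >= 2L && length(y) >= 2L) {
        es <- hedges_g(o, y, conf = conf, n_boot = n_boot, seed = seed)
        row$g <- es$g; row$ci_low <- es$ci_low; row$ci_high <- es$ci_high
      }
      rows <- c(rows, list(row))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlations between metric columns
#'
#' Reshapes an aggregated tidy table to wide format and returns the
#' correlation of two metrics across participants (optionally within a
#' condition), mirroring the exploratory association analyses run on
#' cohort data (e.g. long-range complexity vs the stride-interval scaling
#' exponent).
#'
#' @param aggregated output of [aggregate_segments()].
#' @param metric_x,metric_y metric names.
#' @param condition optional condition filter (default: pool conditions).
#' @return Pearson r (numeric scalar).
#' @export
metric_correlation <- function(aggregated, metric_x, metric_y,
                               condition = NULL) {
  sub <- aggregated
  if (!is.null(condition)) sub <- sub[sub$condition == condition, ]
  x <- sub[sub$metric == metric_x, c("participant", "condition", "value")]
  y <- sub[sub$metric == metric_y, c("participant", "condition", "value")]
  m <- merge(x, y, by = c("participant", "condition"))
  if (nrow(m) < 3L) stop("metric_correlation: fewer than 3 paired values",
                         call. = FALSE)
  stats::cor(m$value.x, m$value.y)
}
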