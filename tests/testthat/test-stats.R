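mk_records <- function() {
  rbind(metric_record("p1", "older", "normal", "segment1", list(aci_ap = 0.020)),
        metric_record("p1", "older", "normal", "segment2", list(aci_ap = 0.024)),
        metric_record("p2", "older", "normal", "segment1", list(aci_ap = 0.030)))
}

test_that("segment aggregation averages pairs and flags singletons", {
  agg <- aggregate_segments(mk_records())
  expect_equal(agg$value[agg$participant == "p1"], 0.022)
  expect_equal(agg$n_segments[agg$participant == "p1"], 2L)
  expect_equal(agg$value[agg$participant == "p2"], 0.030)
  expect_equal(agg$n_segments[agg$participant == "p2"], 1L)
})

test_that("Hedges' g matches summary-level arithmetic and is antisymmetric", {
  # two-point symmetric groups: exactly zero
  es <- hedges_g(c(0, 1), c(0, 1), n_boot = 200)
  expect_equal(es$g, 0)
  expect_lte(es$ci_low, 0); expect_gte(es$ci_high, 0)

  set.seed(5)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  e1 <- hedges_g(a, b, n_boot = 500)
  e2 <- hedges_g(b, a, n_boot = 500)
  expect_equal(e1$g, -e2$g, tolerance = 1e-12)
  expect_true(e1$ci_low <= e1$g && e1$g <= e1$ci_high)

  expect_error(hedges_g(rep(1, 5), rep(1, 6)), "pooled SD")
  expect_error(hedges_g(1, c(1, 2)), "at least 2")
})

test_that("bootstrap CI holds its nominal level on null cohorts", {
  set.seed(17)
  excl <- vapply(1:500, function(i) {
    es <- hedges_g(rnorm(20), rnorm(20), n_boot = 1000, seed = i)
    es$ci_low > 0 || es$ci_high < 0
  }, logical(1))
  expect_lte(mean(excl), 0.03)
})

test_that("relative change reproduces printed condition contrasts", {
  expect_equal(relative_change(0.74, 0.39), -47.29730, tolerance = 1e-5)
  expect_equal(relative_change(0.022, 0.016), -27.27273, tolerance = 1e-5)
  expect_equal(relative_change(3, 3), 0)
  expect_error(relative_change(0, 1), "zero baseline")
})

test_that("cohort table recovers an imposed group difference", {
  set.seed(31)
  recs <- rbind(
    do.call(rbind, lapply(1:60, function(i)
      metric_record(sprintf("o%02d", i), "older", "normal", "segment1",
                    list(aci_ap = rnorm(1, 0.0, 1))))),
    do.call(rbind, lapply(1:42, function(i)
      metric_record(sprintf("y%02d", i), "young", "normal", "segment1",
                    list(aci_ap = rnorm(1, 0.8, 1))))))
  tab <- cohort_table(aggregate_segments(recs), n_boot = 1000)
  expect_equal(tab$n_older, 60L)
  expect_equal(tab$n_young, 42L)
  half_width <- (tab$ci_high - tab$ci_low) / 2
  expect_lt(abs(tab$g - (-0.8)), half_width)

  # single-group cohort: descriptives only, no effect size
  solo <- aggregate_segments(recs[recs$group == "older", ])
  tab2 <- cohort_table(solo, n_boot = 200)
  expect_true(is.na(tab2$g))
  expect_equal(tab2$n_young, 0L)
})

test_that("outlier filter removes extreme rows only when asked", {
  recs <- mk_records()
  recs$value[3] <- 10
  expect_equal(nrow(aggregate_segments(recs)), 2L)
  agg <- aggregate_segments(rbind(recs, recs, recs), outlier_sd = 3)
  expect_true(all(is.finite(agg$value)))
})

test_that("metric correlation helper works on paired wide data", {
  recs <- do.call(rbind, lapply(1:20, function(i) rbind(
    metric_record(sprintf("p%02d", i), "older", "normal", "segment1",
                  list(aci_ap = i + rnorm(1, 0, 0.1))),
    metric_record(sprintf("p%02d", i), "older", "normal", "segment1",
                  list(alpha = i + rnorm(1, 0, 0.1))))))
  r <- metric_correlation(aggregate_segments(recs), "aci_ap", "alpha")
  expect_gt(r, 0.9)
})
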