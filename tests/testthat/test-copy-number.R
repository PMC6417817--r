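test_that("a point-mass cohort gives a single sharp mode at the value", {
  d <- estimate_density(rep(0.8, 60), min_samples = 50)
  pv <- find_peaks_valleys(d)
  expect_equal(nrow(pv$peaks), 1L)
  expect_lt(abs(pv$peaks$location - 0.8), 0.01)
  expect_equal(nrow(pv$valleys), 0L)
})

test_that("density integrates to ~1 and spans [0, 1.1 * max]", {
  set.seed(5)
  for (x in list(rnorm(200, 1, 0.1), abs(rnorm(100, 0, 0.05)),
                 c(rep(0, 50), rnorm(150, 0.5, 0.08)))) {
    x <- pmax(x, 0)
    d <- estimate_density(x, min_samples = 50)
    integral <- sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
    expect_gt(integral, 0.99)
    expect_lt(integral, 1.01)
    expect_equal(d$grid[1], 0)
    expect_equal(max(d$grid), max(x) * 1.1)
  }
})

test_that("small cohorts are refused (population method)", {
  expect_error(estimate_density(rnorm(30, 1, 0.1)), "cohort")
})

test_that("two well-separated components give two modes at their means", {
  set.seed(8)
  x <- c(rnorm(300, 1, 0.1), rnorm(300, 2, 0.1))
  d <- estimate_density(x)
  pv <- find_peaks_valleys(d)
  expect_equal(nrow(pv$peaks), 2L)
  expect_lt(max(abs(pv$peaks$location - c(1, 2))), 0.06)
  # symmetric 50/50 mixture: valley near the midpoint
  expect_gt(pv$valleys$location, 1.4)
  expect_lt(pv$valleys$location, 1.6)
})

test_that("three-component mixture yields three peaks with ascending heights", {
  set.seed(9)
  x <- c(rnorm(60, 0.1, 0.05), rnorm(180, 0.6, 0.05), rnorm(360, 1.1, 0.05))
  x <- pmax(x, 0)
  d <- estimate_density(x)
  pv <- find_peaks_valleys(d)
  expect_equal(nrow(pv$peaks), 3L)
  expect_true(all(diff(pv$peaks$height) > 0))
})

test_that("a flat degenerate density is rejected", {
  d <- structure(list(gene = "g", grid = seq(0, 1, length.out = 64),
                      density = rep(1, 64), bandwidth = 0.1, n = 100),
                 class = "kir_density")
  expect_error(find_peaks_valleys(d), "degenerate")
})

test_that("anchor thresholds bracket the modal diploid peak", {
  set.seed(10)
  x <- rnorm(400, 1, 0.08)
  d <- estimate_density(x, gene = "ANCH")
  pv <- find_peaks_valleys(d)
  th <- derive_thresholds(d, pv, "anchor")
  expect_lt(th$cutoffs[["1/2"]], 1)
  expect_gt(th$cutoffs[["2/3+"]], 1)
  expect_lt(th$cutoffs[["0/1"]], th$cutoffs[["1/2"]])
  expect_equal(as.integer(assign_copy_number(1, th)), 2L)
  expect_equal(th$exclusion_margin, th$cutoffs[["1/2"]] / 50)
})

test_that("high-frequency thresholds fall between the component means", {
  set.seed(12)
  x <- c(abs(rnorm(50, 0, 0.04)), rnorm(150, 0.5, 0.06), rnorm(300, 1, 0.08))
  x <- pmax(x, 0)
  d <- estimate_density(x, gene = "HF")
  pv <- find_peaks_valleys(d)
  th <- derive_thresholds(d, pv, "high_freq")
  expect_gt(th$cutoffs[["0/1"]], 0); expect_lt(th$cutoffs[["0/1"]], 0.5)
  expect_gt(th$cutoffs[["1/2"]], 0.5); expect_lt(th$cutoffs[["1/2"]], 1)
  expect_gt(th$cutoffs[["2/3+"]], 1)
})

test_that("low-frequency cutoffs extrapolate by the inter-peak distance", {
  set.seed(13)
  x <- c(abs(rnorm(700, 0, 0.03)), rnorm(280, 0.5, 0.06), rnorm(20, 1, 0.08))
  x <- pmax(x, 0)
  d <- estimate_density(x, gene = "LF")
  pv <- find_peaks_valleys(d)
  th <- derive_thresholds(d, pv, "low_freq")
  p <- pv$peaks$location
  dist <- p[2] - p[1]
  tol <- 2 * diff(d$grid[1:2]) + 0.02
  # peaks near 0 and 0.5; cutoffs at peak2 + 0.5 and 1.5 inter-peak distances
  expect_lt(abs(th$cutoffs[["1/2"]] - (p[2] + dist / 2)), 1e-9)
  expect_lt(abs(th$cutoffs[["2/3+"]] - (p[2] + 3 * dist / 2)), 1e-9)
  expect_lt(abs(th$cutoffs[["1/2"]] - 0.75), tol + 0.05)
  expect_lt(abs(th$cutoffs[["2/3+"]] - 1.25), tol + 0.1)
  # 0/1 cutoff is the valley between the two real peaks
  expect_gt(th$cutoffs[["0/1"]], 0); expect_lt(th$cutoffs[["0/1"]], 0.5)
})

test_that("incompatible peak counts are reported with the category", {
  set.seed(14)
  x <- rnorm(200, 1, 0.05)
  d <- estimate_density(x, gene = "BAD")
  pv <- find_peaks_valleys(d)
  expect_error(derive_thresholds(d, pv, "high_freq"), "category override")
  expect_error(derive_thresholds(d, pv, "low_freq"), "category override")
})

test_that("assignment is a non-decreasing step function outside excluded zones", {
  th <- structure(list(gene = "g", category = "high_freq",
                       cutoffs = c("0/1" = 0.25, "1/2" = 0.75, "2/3+" = 1.4),
                       exclusion_margin = 0.015),
                  class = "kir_thresholds")
  f <- seq(0, 3, length.out = 10000)
  lab <- assign_copy_number(f, th)
  # brute-force interval scan
  brute <- vapply(f, function(v) {
    if (min(abs(v - th$cutoffs)) < th$exclusion_margin) return(NA_integer_)
    sum(v >= th$cutoffs)
  }, integer(1))
  expect_equal(as.integer(lab), brute)
  ok <- !is.na(lab)
  expect_true(all(diff(lab[ok]) >= 0))
  # a frequency exactly at a cutoff is excluded
  expect_true(is.na(assign_copy_number(0.75, th)))
  expect_error(assign_copy_number(-0.1, th), "negative")
})

test_that("co-segregation rules reproduce the documented combinations", {
  cfg <- kir_default_config()
  calls <- matrix(
    c(2L, 1L, 0L, 3L,   # KIR2DS2
      1L, 1L, 0L, 2L,   # KIR3DS1
      1L, 2L, 0L, 1L,   # KIR2DS4
      0L, 1L, 2L, 1L,   # KIR2DS3
      1L, 1L, 0L, 2L),  # KIR2DS5
    nrow = 4,
    dimnames = list(sprintf("S%d", 1:4),
                    c("KIR2DS2", "KIR3DS1", "KIR2DS4", "KIR2DS3", "KIR2DS5"))
  )
  cn <- structure(list(calls = calls,
                       flag = matrix("measured", 4, 5, dimnames = dimnames(calls)),
                       clamped = matrix(FALSE, 4, 5, dimnames = dimnames(calls)),
                       thresholds = list(), config = cfg),
                  class = "kir_copy_number")
  cn <- infer_cosegregating(cn, cfg$coseg_rules)

  # inverse rule: 2 KIR2DS2 -> 0 KIR2DL3; 1 -> 1; 0 -> 2
  expect_equal(unname(cn$calls[1:3, "KIR2DL3"]), c(0L, 1L, 2L))
  # 3 copies of the source clamps at 0 and flags
  expect_equal(unname(cn$calls[4, "KIR2DL3"]), 0L)
  expect_true(cn$clamped[4, "KIR2DL3"])
  expect_false(any(cn$clamped[1:3, "KIR2DL3"]))
  # direct co-segregation and the two-source sum rule
  expect_equal(unname(cn$calls[, "KIR2DS1"]), unname(calls[, "KIR3DS1"]))
  expect_equal(unname(cn$calls[, "KIR2DL2"]), c(2L, 1L, 0L, 3L))
  expect_equal(unname(cn$calls[, "KIR3DL1"]), unname(calls[, "KIR2DS4"]))
  expect_equal(unname(cn$calls[, "KIR2DL5A"]), c(1L, 2L, 2L, 3L))
  expect_true(all(cn$flag[, "KIR2DL5A"] == "inferred"))
})

test_that("an excluded source excludes the inferred target", {
  cfg <- kir_default_config()
  calls <- matrix(c(NA_integer_, 1L), nrow = 2,
                  dimnames = list(c("S1", "S2"), "KIR2DS2"))
  cn <- structure(list(calls = calls,
                       flag = matrix("measured", 2, 1, dimnames = dimnames(calls)),
                       clamped = matrix(FALSE, 2, 1, dimnames = dimnames(calls)),
                       thresholds = list(), config = cfg),
                  class = "kir_copy_number")
  rules <- list(list(target = "KIR2DL3", sources = "KIR2DS2", op = "inverse"))
  cn <- infer_cosegregating(cn, rules)
  expect_true(is.na(cn$calls["S1", "KIR2DL3"]))
  expect_equal(unname(cn$calls["S2", "KIR2DL3"]), 1L)
})

test_that("a rule referencing an unknown gene is a config error", {
  cn <- structure(list(calls = matrix(1L, 1, 1, dimnames = list("S1", "KIR2DS2")),
                       flag = matrix("measured", 1, 1),
                       clamped = matrix(FALSE, 1, 1),
                       thresholds = list(), config = kir_default_config()),
                  class = "kir_copy_number")
  expect_error(infer_cosegregating(
    cn, list(list(target = "X", sources = "NOPE", op = "sum"))), "unknown gene")
})

test_that("config validation catches orphan inferred genes and bad categories", {
  expect_error(kir_config(c(A = "weird")), "categories")
  expect_error(kir_config(c(A = "inferred")), "without a co-segregation rule")
  expect_error(kir_config(
    c(A = "inferred", B = "anchor"),
    coseg_rules = list(list(target = "A", sources = "B", op = "sum"),
                       list(target = "A", sources = "B", op = "sum"))
  ), "more than one")
})

test_that("cohort calling recovers simulated copy numbers", {
  study <- small_study()
  cn <- call_copy_numbers(study$freqs, kir_default_config())
  acc <- call_accuracy(cn, study$truth)
  expect_gt(acc$measured_accuracy, 0.9)
  expect_lt(acc$excluded_fraction, 0.1)
  expect_equal(acc$inferred_accuracy, 1)
  expect_true(all(cn$flag[, "KIR2DS1"] == "inferred"))
  expect_true(all(cn$flag[, "KIR3DL3"] == "measured"))
})
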