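test_that("autoscaling computes sample statistics and drops constant columns", {
  b <- feature_block("x", cbind(a = c(2, 4, 6), b = c(1, 1, 1), c = c(0, 1, 2)))
  m <- autoscale_fit(b)
  expect_equal(unname(m$means[1]), 4)
  expect_equal(unname(m$sds[1]), 2)          # n-1 denominator
  expect_equal(unname(m$keep), c(TRUE, FALSE, TRUE))
  out <- autoscale_apply(b, m)
  expect_equal(ncol(out$matrix), 2L)         # constant column dropped
  expect_equal(unname(out$matrix[, 1]), c(-1, 0, 1))
  expect_match(out$provenance, "autoscale", all = FALSE)

  expect_error(autoscale_fit(feature_block("x", matrix(1:3, 1))), "at least 2")
  expect_error(autoscale_apply(feature_block("x", matrix(1:6, 3, 2)), m),
               "does not match")

  # a new sample equal to the training mean vector maps to all zeros
  mean_row <- feature_block("x", matrix(m$means, 1))
  expect_equal(unname(autoscale_apply(mean_row, m)$matrix[1, ]), c(0, 0))
})

test_that("autoscaled training data has column means 0 and sds 1 to 1e-9", {
  ds <- small_corpus()
  sc <- autoscale_fit(ds$blocks$ims)
  out <- autoscale_apply(ds$blocks$ims, sc)
  expect_lt(max(abs(colMeans(out$matrix))), 1e-9)
  expect_lt(max(abs(apply(out$matrix, 2, stats::sd) - 1)), 1e-9)
})

test_that("snv centers and scales rows, idempotently and affine-invariantly", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  for (i in 1:20) {
    x <- stats::rnorm(50, mean = stats::runif(1, -5, 5), sd = stats::runif(1, 0.1, 3))
    y <- snv(x)
    expect_equal(mean(y), 0, tolerance = 1e-12)
    expect_equal(stats::sd(y), 1, tolerance = 1e-12)
    expect_equal(snv(y), y, tolerance = 1e-12)                    # idempotence
    a <- stats::runif(1, 0.1, 10); b <- stats::rnorm(1, 0, 100)
    expect_equal(snv(a * x + b), y, tolerance = 1e-9)             # affine invariance
  }
  expect_error(snv(rep(2, 10)), "constant")
  expect_error(snv(3), "at least 2")
})

test_that("resampling is exact on identical grids and for linear signals", {
  g1 <- axis_grid(seq(0, 10, by = 0.5), "s")
  v <- stats::rnorm(length(g1$values))
  expect_equal(resample_signal(v, g1, g1), v)
  g2 <- axis_grid(seq(0.3, 9.7, by = 0.21), "s")
  lin <- 3 * g1$values - 2
  expect_equal(resample_signal(lin, g1, g2), 3 * g2$values - 2, tolerance = 1e-12)
  expect_error(resample_signal(v, g1, axis_grid(c(5, 11), "s")), "extrapolation")
  expect_error(resample_signal(v, g1, axis_grid(c(5, 6), "ms")), "units")
})

test_that("peak detection finds resolved peaks above the floor, in drift order", {
  p1 <- two_peak_plasmagram(a1 = 5, a2 = 0)
  pk <- detect_peaks(p1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$drift_time, 8.7, tolerance = 0.11)

  # a 0.5 nA peak is excluded at the default 1 nA floor
  expect_equal(nrow(detect_peaks(two_peak_plasmagram(a1 = 0.5, a2 = 0))), 0L)

  pk2 <- detect_peaks(two_peak_plasmagram(a1 = 5, a2 = 3))
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$drift_time, c(8.7, 11.2), tolerance = 0.11)  # sorted by drift
  expect_equal(pk2$reduced_mobility, 2.45 * 8 / c(8.7, 11.2), tolerance = 0.03)
})

test_that("peak counts match the generated ground truth across 100 seeds", {
  tpl <- templates()$tatp
  for (seed in 1:100) {
    pk <- detect_peaks(generate_plasmagram(tpl, 50, seed = seed))
    expect_equal(nrow(pk), 2L)  # reactant-ion peak + TATP peak, both above 1 nA
  }
})

test_that("drift-to-K0 conversion is an inverse proportionality through the reference", {
  cal <- mobility_calibration(reference_peak_K0 = 2.06, reference_drift_time = 10)
  expect_equal(drift_to_K0(10, cal), 2.06)
  expect_equal(drift_to_K0(20, cal), 1.03)  # double drift time, half mobility
  expect_error(drift_to_K0(0, cal), "> 0")
  expect_error(drift_to_K0(-3, cal), "> 0")
})

test_that("retention-time extraction returns the tallest apex and rejects flat traces", {
  tt <- seq(0, 120, by = 0.5)
  expect_equal(extract_rt(chromatogram(tt, exp(-((tt - 60)^2) / 8))), 60,
               tolerance = 0.5)
  two <- exp(-((tt - 30)^2) / 8) + 2 * exp(-((tt - 90)^2) / 8)
  expect_equal(extract_rt(chromatogram(tt, two)), 90, tolerance = 0.5)
  expect_error(extract_rt(chromatogram(tt, rep(0, length(tt)))), "flat")
})
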