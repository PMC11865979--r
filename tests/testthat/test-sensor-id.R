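test_that("reduced-mobility windows are symmetric and multiplicative", {
  lib <- list(rm_library_entry("tatp", 2.06))
  mk <- function(k0, int = 3) data.frame(drift_time = 8, intensity = int,
                                         reduced_mobility = k0)
  # window is [2.0188, 2.1012] at 2.06 +/- 2%
  expect_true(rm_identify(mk(2.06), lib)$matched)
  expect_true(rm_identify(mk(2.0188), lib)$matched)    # closed lower bound
  expect_true(rm_identify(mk(2.1012), lib)$matched)    # closed upper bound
  expect_false(rm_identify(mk(2.102), lib)$matched)
  expect_false(rm_identify(mk(2.018), lib)$matched)
  expect_false(rm_identify(mk(2.06, int = 0.8), lib)$matched)  # below 1 nA floor
  eps <- 1e-6
  for (tol in c(0.01, 0.02, 0.05)) {
    l <- list(rm_library_entry("x", 2.06, tolerance = tol))
    expect_true(rm_identify(mk(2.06 * (1 + tol - eps)), l)$matched)
    expect_true(rm_identify(mk(2.06 * (1 - tol + eps)), l)$matched)
    expect_false(rm_identify(mk(2.06 * (1 + tol + eps)), l)$matched)
    expect_false(rm_identify(mk(2.06 * (1 - tol - eps)), l)$matched)
  }
  expect_error(rm_identify(mk(2), list()), "non-empty")
})

test_that("the two-peak DMMP mode requires both library mobilities", {
  lib2 <- list(rm_library_entry("dmmp", 1.81, required_peaks = 2L),
               rm_library_entry("dmmp", 1.43, required_peaks = 2L))
  one <- data.frame(drift_time = 9.7, intensity = 3, reduced_mobility = 1.81)
  both <- rbind(one, data.frame(drift_time = 12.3, intensity = 2,
                                reduced_mobility = 1.43))
  expect_false(any(rm_identify(one, lib2)$matched))
  expect_true(all(rm_identify(both, lib2)$matched))
})

test_that("retention-time windows are closed mu +/- k sigma intervals", {
  m <- rt_model("x", mu = 60, sigma = 1, k = 3)
  expect_true(rt_detect(62, m))
  expect_false(rt_detect(64, m))
  expect_true(rt_detect(63, m))   # exactly mu + k sigma: closed
  expect_true(rt_detect(57, m))
  expect_error(rt_model("x", 60, 0), "> 0")
})

test_that("Pearson matching is affine-invariant and near zero for foreign bands", {
  wl <- axis_grid(seq(7.4, 10.7, by = 0.01), "um")
  shape <- exp(-((wl$values - 8.5)^2) / 0.03) + 0.5 * exp(-((wl$values - 9.9)^2) / 0.05)
  ref <- spectral_reference("a", ir_spectrum(wl, shape))
  same <- pearson_match(ir_spectrum(wl, shape), ref)
  expect_equal(same$r, 1, tolerance = 1e-12)
  expect_true(same$matched)
  offset <- pearson_match(ir_spectrum(wl, 3 * shape + 100), ref)
  expect_equal(offset$r, 1, tolerance = 1e-12)  # SNV removes offset and scale
  other <- exp(-((wl$values - 7.8)^2) / 0.02)
  far <- pearson_match(ir_spectrum(wl, other), ref)
  expect_lt(abs(far$r), 0.3)
  expect_false(far$matched)
  expect_error(pearson_match(ir_spectrum(wl, rep(1, length(wl$values))), ref),
               "constant")
})

test_that("the LDA baseline separates well-separated classes and validates input", {
  ds <- cached("lda_corpus", function() {
    generate_training_corpus(templates()[c("dmmp", "acetone")], n_per_analyte = 3,
                             concentrations = c(5.7, 50), seed = 21)
  })
  fit <- lda_fit(ds, blocks = "qepas", pca_dims = 5)
  expect_equal(lda_predict(fit, ds), ds$labels)  # separable: 100% training accuracy

  # prediction is invariant to a consistent feature-order permutation
  set.seed(1)
  perm <- sample(ncol(ds$blocks$qepas$matrix))
  ds_perm <- labelled_dataset(
    list(qepas = feature_block("qepas", ds$blocks$qepas$matrix[, perm])),
    ds$labels, ds$concentrations)
  fit_perm <- lda_fit(ds_perm, blocks = "qepas", pca_dims = 5)
  expect_equal(lda_predict(fit_perm, ds_perm), lda_predict(fit, ds))

  one_class <- labelled_dataset(ds$blocks, rep("dmmp", length(ds$labels)))
  expect_error(lda_fit(one_class), "2 classes")
})

test_that("sequential GC-QEPAS identification screens by RT then confirms by spectrum", {
  wl <- axis_grid(seq(7.4, 10.7, by = 0.01), "um")
  shape <- exp(-((wl$values - 8.5)^2) / 0.03)
  refs <- list(a = spectral_reference("a", ir_spectrum(wl, shape)))
  models <- list(a = rt_model("a", mu = 60, sigma = 1))
  sp_good <- ir_spectrum(wl, shape + stats::rnorm(length(wl$values), 0, 0.001))
  expect_true(gcqepas_sequential_id(61, sp_good, models, refs)$matched)
  expect_false(gcqepas_sequential_id(70, sp_good, models, refs)$matched)   # RT screens
  sp_bad <- ir_spectrum(wl, exp(-((wl$values - 9.9)^2) / 0.05))
  expect_false(gcqepas_sequential_id(60, sp_bad, models, refs)$matched)    # spectrum vetoes
  expect_error(gcqepas_sequential_id(60, sp_good, models,
                                     list(b = spectral_reference("b", ir_spectrum(wl, shape)))),
               "same analytes")
})

test_that("sequential identification keeps the cross-analyte false-positive rate < 5%", {
  tpl <- templates()
  ins <- fusion_instrument()
  # references from noiseless templates; RT windows from the template model
  # with a sigma floor at half the chromatogram sampling step
  refs <- lapply(tpl, function(t) {
    g <- generate_gcqepas(t, 500, noise_model(0, 0, 0), seed = 1)
    spectral_reference(t$name, g$spectrum)
  })
  models <- lapply(tpl, function(t)
    rt_model(t$name, t$rt_mean, max(t$rt_sd, 0.25), k = 3))
  n_fp <- 0L; n_checks <- 0L
  for (nm in names(tpl)) {
    for (i in 1:25) {
      cc <- c(2.8, 5.7, 50, 500)[(i %% 4) + 1]
      g <- generate_gcqepas(tpl[[nm]], cc,
                            seed = 7000 + 100 * match(nm, names(tpl)) + i)
      res <- gcqepas_sequential_id(extract_rt(g$chromatogram), g$spectrum,
                                   models, refs)
      wrong <- res$analyte != nm
      n_fp <- n_fp + sum(res$matched[wrong])
      n_checks <- n_checks + sum(wrong)
    }
  }
  expect_lt(n_fp / n_checks, 0.05)
})
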