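test_that("generators are deterministic and reject nonpositive concentrations", {
  tpl <- templates()$dmmp
  a <- generate_plasmagram(tpl, 5.7, seed = 42)
  b <- generate_plasmagram(tpl, 5.7, seed = 42)
  expect_identical(a$current, b$current)  # bit-identical
  g1 <- generate_gcqepas(tpl, 5.7, seed = 42)
  g2 <- generate_gcqepas(tpl, 5.7, seed = 42)
  expect_identical(g1$spectrum$signal, g2$spectrum$signal)
  expect_identical(g1$chromatogram$signal, g2$chromatogram$signal)
  c_ <- generate_plasmagram(tpl, 5.7, seed = 43)
  expect_false(identical(a$current, c_$current))
  expect_error(generate_plasmagram(tpl, 0, seed = 1), "> 0")
  expect_error(generate_gcqepas(tpl, -1, seed = 1), "> 0")
})

test_that("the secondary DMMP peak appears only at high concentration", {
  tpl <- templates()$dmmp
  low <- detect_peaks(generate_plasmagram(tpl, 5.7, seed = 9))
  high <- detect_peaks(generate_plasmagram(tpl, 500, seed = 9))
  # reactant-ion peak plus one analyte peak below the gate, two above it
  expect_equal(nrow(low), 2L)
  expect_equal(nrow(high), 3L)
  k0 <- sort(high$reduced_mobility)
  expect_equal(k0[1], 1.43, tolerance = 0.02)
  expect_equal(k0[2], 1.81, tolerance = 0.02)
})

test_that("analyte peak amplitude is nondecreasing in concentration (fixed seed)", {
  for (nm in c("dmmp", "acetone", "tatp")) {
    tpl <- templates()[[nm]]
    td <- 2.45 * 8 / tpl$ims_peaks$reduced_mobility[1]
    grid <- fusion_instrument()$drift_grid$values
    idx <- which.min(abs(grid - td))
    amps <- vapply(c(1, 2.8, 5.7, 20, 50, 200, 500), function(cc) {
      generate_plasmagram(tpl, cc, seed = 5)$current[idx]
    }, 0)
    expect_true(all(diff(amps) >= 0), info = nm)
  }
})

test_that("generated amplitudes straddle the 1 nA floor across the ppb range", {
  tpl <- templates()$tatp
  noise0 <- noise_model(0, 0, 0)
  pk_low <- detect_peaks(generate_plasmagram(tpl, 0.5, noise0, seed = 1),
                         min_intensity = 0)
  a_low <- pk_low$intensity[abs(pk_low$reduced_mobility - 2.06) < 0.05]
  expect_lt(a_low, 1)  # below the identification floor near detection limit
  pk_high <- detect_peaks(generate_plasmagram(tpl, 50, noise0, seed = 1))
  a_high <- pk_high$intensity[abs(pk_high$reduced_mobility - 2.06) < 0.05]
  expect_gt(a_high, 1)
})

test_that("retention-time apex follows the stated sampling distribution", {
  tpl <- analyte_template("rtcheck", templates()$dmmp$ims_peaks,
                          rt_mean = 60, rt_sd = 0.5,
                          ir_bands = templates()$dmmp$ir_bands)
  nz <- noise_model(baseline_sd = 0.001, drift_amplitude = 0, rt_jitter_sd = 0)
  apices <- vapply(seq_len(1000), function(i) {
    extract_rt(generate_gcqepas(tpl, 50, nz, seed = i)$chromatogram)
  }, 0)
  # empirical sd inflated only by the 0.5 s sampling grid
  expect_gt(stats::sd(apices), 0.4)
  expect_lt(stats::sd(apices), 0.6)
  expect_equal(mean(apices), 60, tolerance = 0.1)
})

test_that("zero noise yields exactly the analytic band sum", {
  tpl <- templates()$acetone
  ins <- fusion_instrument()
  g <- generate_gcqepas(tpl, 50, noise_model(0, 0, 0), seed = 1)
  wl <- ins$wavelength_grid$values
  expected <- 0
  for (i in seq_len(nrow(tpl$ir_bands))) {
    b <- tpl$ir_bands[i, ]
    expected <- expected + b$relative_amplitude *
      exp(-((wl - b$center)^2) / (2 * b$width^2))
  }
  expected <- ins$spectrum_amplitude * (50 / (50 + ins$saturation_ppb)) * expected
  expect_equal(g$spectrum$signal, expected, tolerance = 1e-12)
})

test_that("training corpora are balanced, seeded and include the study concentrations", {
  tpl <- templates()
  ds <- generate_training_corpus(tpl[c("acetone", "dmmp", "tatp")],
                                 n_per_analyte = 5, seed = 2)
  expect_equal(length(ds$labels), 60L)  # 3 analytes x 4 concentrations x 5
  expect_setequal(unique(ds$concentrations), c(2.8, 5.7, 50, 500))
  expect_equal(unname(table(ds$labels)["dmmp"]), 20L, ignore_attr = TRUE)
  ds2 <- generate_training_corpus(tpl[c("acetone", "dmmp", "tatp")],
                                  n_per_analyte = 5, seed = 3)
  expect_equal(dim(ds2$blocks$ims$matrix), dim(ds$blocks$ims$matrix))
  expect_false(identical(ds$blocks$ims$matrix, ds2$blocks$ims$matrix))
  expect_error(generate_training_corpus(tpl$dmmp, concentrations = numeric(), seed = 1),
               "non-empty")
  expect_error(generate_training_corpus(tpl$dmmp, n_per_analyte = 0, seed = 1),
               ">= 1")
})

test_that("spectra separate analytes: own-template r > 0.9, cross-template r < 0.5", {
  tpl <- templates()
  ins <- fusion_instrument()
  wl <- ins$wavelength_grid$values
  band_sum <- function(t) {
    s <- 0
    for (i in seq_len(nrow(t$ir_bands))) {
      b <- t$ir_bands[i, ]
      s <- s + b$relative_amplitude * exp(-((wl - b$center)^2) / (2 * b$width^2))
    }
    s
  }
  for (seed in 1:5) {
    for (nm in names(tpl)) {
      sp <- generate_gcqepas(tpl[[nm]], 2.8, seed = seed * 100 + match(nm, names(tpl)))
      for (other in names(tpl)) {
        r <- stats::cor(sp$spectrum$signal, band_sum(tpl[[other]]))
        if (other == nm) expect_gt(r, 0.9) else expect_lt(r, 0.5)
      }
    }
  }
})
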