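# Seeded synthetic-data generators for the three sensor channels.
#
# RNG discipline: each generator consumes draws in a fixed order (gain,
# baseline, peak apex, trace noise) so that the same seed yields bit-identical
# output and amplitude remains nondecreasing in concentration (concentration
# gates change no draw order; peaks excluded by the gate still leave the
# stream untouched because amplitudes are computed analytically).

saturating_amplitude <- function(concentration, saturation_ppb) {
  concentration / (concentration + saturation_ppb)
}

k0_to_drift <- function(K0, calib) calib$reference_peak_K0 * calib$reference_drift_time / K0

#' Generate a synthetic plasmagram
#'
#' Gaussian analyte peaks at the drift times implied by each template reduced
#' mobility whose `min_concentration` gate admits the requested concentration,
#' plus the reactant-ion peak at the calibration reference position, a shared
#' baseline offset and scan-averaged white noise. Peak amplitude follows the
#' saturating law `relative_amplitude * amplitude_max * c / (c + k)` times the
#' shared gain factor, so it is nondecreasing in concentration and straddles
#' the 1 nA identification floor across the ppb range.
#'
#' @param template An [analyte_template()].
#' @param concentration Concentration in ppb, > 0.
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical inputs give bit-identical traces.
#' @param instrument A [fusion_instrument()].
#' @param gain Optional shared per-sample gain factor; drawn from the noise
#'   model when `NULL`. Passed explicitly by the scene/corpus generators so
#'   both channels of one sample share it.
#' @return A [plasmagram()].
#' @export
generate_plasmagram <- function(template, concentration, noise = noise_model(),
                                seed = 1, instrument = fusion_instrument(),
                                gain = NULL) {
  if (!is.finite(concentration) || concentration <= 0)
    stopf("concentration must be > 0")
  dt <- instrument$drift_grid$values
  with_seed(seed, {
    g <- gain %||% exp(stats::rnorm(1, 0, noise$drift_amplitude))
    baseline <- stats::rnorm(1, 0, noise$baseline_sd)
    white <- stats::rnorm(length(dt), 0, noise$baseline_sd / sqrt(instrument$scans))
    amp_frac <- saturating_amplitude(concentration, instrument$saturation_ppb)
    trace <- g * instrument$rip_amplitude *
      gaussian_profile(dt, instrument$calibration$reference_drift_time,
                       instrument$peak_width)
    for (i in seq_len(nrow(template$ims_peaks))) {
      pk <- template$ims_peaks[i, ]
      if (concentration >= pk$min_concentration) {
        td <- k0_to_drift(pk$reduced_mobility, instrument$calibration)
        trace <- trace + g * pk$relative_amplitude * instrument$amplitude_max *
          amp_frac * gaussian_profile(dt, td, instrument$peak_width)
      }
    }
    plasmagram(instrument$drift_grid, trace + baseline + white)
  })
}

#' Generate a synthetic GC-QEPAS reading (chromatogram + IR spectrum)
#'
#' The chromatogram holds one dominant Gaussian peak whose apex is drawn from
#' `Normal(rt_mean, rt_sd)` plus `Normal(0, rt_jitter_sd)` jitter. The
#' spectrum is the sum of the template bands scaled by the saturating
#' concentration law and the shared gain, plus an additive noise floor and
#' relative-intensity noise proportional to the rms signal. With the noise
#' model all zeros the spectrum equals the analytic band sum exactly.
#'
#' @inheritParams generate_plasmagram
#' @return A list with elements `chromatogram` and `spectrum`.
#' @export
generate_gcqepas <- function(template, concentration, noise = noise_model(),
                             seed = 1, instrument = fusion_instrument(),
                             gain = NULL) {
  if (!is.finite(concentration) || concentration <= 0)
    stopf("concentration must be > 0")
  tt <- instrument$time_grid$values
  wl <- instrument$wavelength_grid$values
  with_seed(seed, {
    g <- gain %||% exp(stats::rnorm(1, 0, noise$drift_amplitude))
    apex <- template$rt_mean + stats::rnorm(1, 0, template$rt_sd) +
      stats::rnorm(1, 0, noise$rt_jitter_sd)
    chrom_noise <- stats::rnorm(length(tt), 0, noise$baseline_sd)
    spec_white <- stats::rnorm(length(wl))
    amp_frac <- saturating_amplitude(concentration, instrument$saturation_ppb)

    chrom_sig <- g * instrument$chrom_amplitude * amp_frac *
      gaussian_profile(tt, apex, instrument$chrom_width) + chrom_noise

    band_sum <- rep(0, length(wl))
    for (i in seq_len(nrow(template$ir_bands))) {
      b <- template$ir_bands[i, ]
      band_sum <- band_sum + b$relative_amplitude *
        gaussian_profile(wl, b$center, b$width)
    }
    sig <- g * instrument$spectrum_amplitude * amp_frac * band_sum
    noise_sd <- sqrt((noise$baseline_sd * instrument$qepas_floor_ratio)^2 +
                     (noise$baseline_sd * instrument$qepas_rin_ratio *
                        sqrt(mean(sig^2)))^2)
    list(chromatogram = chromatogram(instrument$time_grid, chrom_sig),
         spectrum = ir_spectrum(instrument$wavelength_grid,
                                sig + noise_sd * spec_white))
  })
}

#' Generate a mock scene: co-deployed IMS and GC-QEPAS readings per analyte
#'
#' @param analytes List of `list(template = , concentration = )` entries.
#' @param ims_position,gc_position [sensor_position()]s of the two sensors.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param instrument A [fusion_instrument()].
#' @param timestamp Base acquisition time (s); both readings of a sample share it.
#' @return List of [sample_record()]s (empty for an empty analyte list).
#' @export
generate_scene <- function(analytes, ims_position, gc_position,
                           noise = noise_model(), seed = 1,
                           instrument = fusion_instrument(), timestamp = 0) {
  if (!inherits(ims_position, "sensor_position") ||
      !inherits(gc_position, "sensor_position"))
    stopf("positions must be sensor_position objects")
  out <- vector("list", length(analytes))
  for (i in seq_along(analytes)) {
    a <- analytes[[i]]
    s <- derive_seed(seed, i)
    g <- with_seed(s, exp(stats::rnorm(1, 0, noise$drift_amplitude)))
    pg <- generate_plasmagram(a$template, a$concentration, noise,
                              seed = derive_seed(s, 1), instrument, gain = g)
    gq <- generate_gcqepas(a$template, a$concentration, noise,
                           seed = derive_seed(s, 2), instrument, gain = g)
    out[[i]] <- sample_record(
      label = a$template$name, concentration = a$concentration,
      readings = list(
        sensor_reading("IMS", ims_position, pg, timestamp),
        sensor_reading("GCQEPAS", gc_position, gq, timestamp)))
  }
  out
}

#' Generate a balanced labelled training corpus
#'
#' Crosses analytes with concentrations, `n_per_analyte` replicates per cell,
#' each replicate generated under a fresh derived sub-seed. Default
#' concentration set: 2.8, 5.7, 50 and 500 ppb (the two low values are study
#' concentrations; the upper two span "higher concentrations"). Blocks
#' produced: `ims` (plasmagram trace), `qepas` (IR spectrum), `rt` (scalar
#' retention time via [extract_rt()]).
#'
#' @param templates An [analyte_template()] or list of them.
#' @param n_per_analyte Replicates per analyte x concentration cell, >= 1.
#' @param concentrations Non-empty numeric vector of ppb values.
#' @param seed Integer seed.
#' @param noise A [noise_model()].
#' @param instrument A [fusion_instrument()].
#' @return A [labelled_dataset()] with
#'   `length(templates) * length(concentrations) * n_per_analyte` rows in
#'   analyte-major, then concentration-major order.
#' @examples
#' tpl <- default_templates()
#' ds <- generate_training_corpus(tpl$dmmp, n_per_analyte = 2,
#'                                concentrations = c(2.8, 50), seed = 7)
#' @export
generate_training_corpus <- function(templates, n_per_analyte = 10,
                                     concentrations = c(2.8, 5.7, 50, 500),
                                     seed = 1, noise = noise_model(),
                                     instrument = fusion_instrument()) {
  if (inherits(templates, "analyte_template")) templates <- list(templates)
  if (length(concentrations) == 0) stopf("concentration list must be non-empty")
  if (n_per_analyte < 1) stopf("n_per_analyte must be >= 1")
  ims_rows <- list(); sp_rows <- list(); rt_vals <- c()
  labels <- c(); conc_out <- c()
  idx <- 0L
  for (tpl in templates) {
    for (cc in concentrations) {
      for (r in seq_len(n_per_analyte)) {
        idx <- idx + 1L
        s <- derive_seed(seed, idx)
        g <- with_seed(s, exp(stats::rnorm(1, 0, noise$drift_amplitude)))
        pg <- generate_plasmagram(tpl, cc, noise, seed = derive_seed(s, 1),
                                  instrument, gain = g)
        gq <- generate_gcqepas(tpl, cc, noise, seed = derive_seed(s, 2),
                               instrument, gain = g)
        ims_rows[[idx]] <- pg$current
        sp_rows[[idx]] <- gq$spectrum$signal
        rt_vals[idx] <- extract_rt(gq$chromatogram)
        labels[idx] <- tpl$name
        conc_out[idx] <- cc
      }
    }
  }
  labelled_dataset(
    blocks = list(
      ims = feature_block("ims", do.call(rbind, ims_rows),
                          variable_axis = instrument$drift_grid),
      qepas = feature_block("qepas", do.call(rbind, sp_rows),
                            variable_axis = instrument$wavelength_grid),
      rt = feature_block("rt", matrix(rt_vals, ncol = 1))),
    labels = labels, concentrations = conc_out)
}
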