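#' Analyte template for the synthetic-data generator
#'
#' Describes how an analyte appears on the three sensor channels: IMS peaks by
#' reduced mobility (with a minimum concentration gating each peak -- DMMP's
#' secondary peak appears only at high concentration), the GC retention-time
#' distribution, and additive IR absorption bands. Templates are configuration
#' data (see `inst/extdata/templates.yaml`), not code constants.
#'
#' @param name Analyte name.
#' @param ims_peaks Data frame with columns `reduced_mobility` (cm2/V/s),
#'   `relative_amplitude`, `min_concentration` (ppb; 0 = always present).
#' @param rt_mean,rt_sd Retention-time mean and Gaussian scatter (s), `rt_sd > 0`.
#' @param ir_bands Data frame with columns `center` (um, within 7.4--10.7),
#'   `width` (um), `relative_amplitude`.
#' @return An object of class `analyte_template`.
#' @export
analyte_template <- function(name, ims_peaks, rt_mean, rt_sd, ir_bands) {
  ims_peaks <- as.data.frame(ims_peaks)
  ir_bands <- as.data.frame(ir_bands)
  need_p <- c("reduced_mobility", "relative_amplitude", "min_concentration")
  need_b <- c("center", "width", "relative_amplitude")
  if (nrow(ims_peaks) == 0 || !all(need_p %in% names(ims_peaks)))
    stopf("ims_peaks must be non-empty with columns: %s", paste(need_p, collapse = ", "))
  if (!all(need_b %in% names(ir_bands)))
    stopf("ir_bands must have columns: %s", paste(need_b, collapse = ", "))
  if (!is.finite(rt_sd) || rt_sd <= 0) stopf("rt_sd must be > 0")
  if (any(ir_bands$center < 7.4 - 1e-9) || any(ir_bands$center > 10.7 + 1e-9))
    stopf("ir band centers must lie within [7.4, 10.7] um")
  if (any(ims_peaks$reduced_mobility <= 0)) stopf("reduced mobilities must be > 0")
  structure(list(name = name, ims_peaks = ims_peaks,
                 rt_mean = rt_mean, rt_sd = rt_sd, ir_bands = ir_bands),
            class = "analyte_template")
}

#' Measurement-noise model for the synthetic generator
#'
#' Emulates run-to-run variation ("different operators ... different days ...
#' different batches") with three knobs. `baseline_sd` (nA for the IMS trace;
#' scaled per channel, see the methods vignette) sets additive noise floors
#' and the shared baseline offset; `drift_amplitude` is the log-sd of the
#' shared per-sample instrument gain factor applied to every channel;
#' `rt_jitter_sd` (s) adds retention-time jitter beyond the template scatter.
#' All zeros give exactly the analytic signal model.
#'
#' @param baseline_sd Additive noise scale, >= 0. Default 0.002 nA.
#' @param drift_amplitude Log-sd of the shared gain drift, >= 0. Default 0.15.
#' @param rt_jitter_sd Retention-time jitter sd (s), >= 0. Default 0.05.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(baseline_sd = 0.002, drift_amplitude = 0.15,
                        rt_jitter_sd = 0.05) {
  v <- c(baseline_sd, drift_amplitude, rt_jitter_sd)
  if (any(!is.finite(v)) || any(v < 0)) stopf("noise model fields must be >= 0")
  structure(list(baseline_sd = baseline_sd, drift_amplitude = drift_amplitude,
                 rt_jitter_sd = rt_jitter_sd),
            class = "noise_model")
}

#' Single-point reduced-mobility calibration
#'
#' Maps drift time to reduced mobility K0 through one reference peak:
#' `K0 = reference_peak_K0 * reference_drift_time / drift_time`. The default
#' reference is the negative-mode reactant-ion peak at K0 = 2.45 cm2/V/s,
#' placed at 8 ms. The full Mason-Schamp conversion is out of scope; pressure
#' and temperature ride on the [plasmagram()] for a future implementation.
#'
#' @param reference_peak_K0 Reference reduced mobility (cm2/V/s), > 0.
#' @param reference_drift_time Reference drift time (ms), > 0.
#' @return An object of class `mobility_calibration`.
#' @export
mobility_calibration <- function(reference_peak_K0 = 2.45, reference_drift_time = 8.0) {
  if (!is.finite(reference_peak_K0) || reference_peak_K0 <= 0)
    stopf("reference_peak_K0 must be > 0")
  if (!is.finite(reference_drift_time) || reference_drift_time <= 0)
    stopf("reference_drift_time must be > 0")
  structure(list(reference_peak_K0 = reference_peak_K0,
                 reference_drift_time = reference_drift_time),
            class = "mobility_calibration")
}

#' Instrument model for the synthetic generator
#'
#' Sampling grids and response constants of the emulated IMS and GC-QEPAS
#' instruments. See the methods vignette for the rationale behind each
#' default.
#'
#' @param drift_grid IMS drift-time [axis_grid()] (ms).
#' @param wavelength_grid IR [axis_grid()] (um).
#' @param time_grid Chromatogram [axis_grid()] (s).
#' @param calibration A [mobility_calibration()]; its reference peak is the
#'   generated reactant-ion peak.
#' @param rip_amplitude Reactant-ion peak amplitude (nA).
#' @param peak_width IMS peak Gaussian sd (ms).
#' @param amplitude_max Analyte IMS peak amplitude at saturation (nA).
#' @param saturation_ppb Half-saturation constant of the amplitude law
#'   `a * c / (c + saturation_ppb)`.
#' @param scans Number of averaged IMS scans; white noise scales by
#'   `1/sqrt(scans)`.
#' @param spectrum_amplitude IR band amplitude at saturation (a.u.).
#' @param qepas_floor_ratio IR additive noise floor as a fraction of
#'   `baseline_sd`.
#' @param qepas_rin_ratio IR relative-intensity noise (fraction of the rms
#'   signal) per unit `baseline_sd`.
#' @param chrom_amplitude Chromatogram peak height at saturation (a.u.).
#' @param chrom_width Chromatogram peak Gaussian sd (s).
#' @return An object of class `fusion_instrument`.
#' @export
fusion_instrument <- function(drift_grid = axis_grid(seq(4, 16, by = 0.1), "ms"),
                              wavelength_grid = axis_grid(seq(7.4, 10.7, by = 0.01), "um"),
                              time_grid = axis_grid(seq(0, 180, by = 0.5), "s"),
                              calibration = mobility_calibration(),
                              rip_amplitude = 8, peak_width = 0.25,
                              amplitude_max = 10, saturation_ppb = 20,
                              scans = 100, spectrum_amplitude = 0.24,
                              qepas_floor_ratio = 0.01, qepas_rin_ratio = 0.75,
                              chrom_amplitude = 1, chrom_width = 0.8) {
  structure(list(drift_grid = drift_grid, wavelength_grid = wavelength_grid,
                 time_grid = time_grid, calibration = calibration,
                 rip_amplitude = rip_amplitude, peak_width = peak_width,
                 amplitude_max = amplitude_max, saturation_ppb = saturation_ppb,
                 scans = scans, spectrum_amplitude = spectrum_amplitude,
                 qepas_floor_ratio = qepas_floor_ratio,
                 qepas_rin_ratio = qepas_rin_ratio,
                 chrom_amplitude = chrom_amplitude, chrom_width = chrom_width),
            class = "fusion_instrument")
}

#' Load analyte templates, noise model and instrument from a YAML config
#'
#' @param path Path to a YAML file; defaults to the configuration shipped with
#'   the package (acetone, DMMP, TATP and a toluene confuser).
#' @return A list with elements `analytes` (named list of
#'   [analyte_template()]s), `noise` ([noise_model()]) and `instrument`
#'   ([fusion_instrument()]).
#' @export
load_templates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "templates.yaml", package = "chemfuse")
  if (!file.exists(path)) stopf("template config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  analytes <- lapply(names(cfg$analytes), function(nm) {
    a <- cfg$analytes[[nm]]
    analyte_template(
      name = nm,
      ims_peaks = do.call(rbind, lapply(a$ims_peaks, as.data.frame)),
      rt_mean = a$rt_mean, rt_sd = a$rt_sd,
      ir_bands = do.call(rbind, lapply(a$ir_bands, as.data.frame)))
  })
  names(analytes) <- names(cfg$analytes)
  nz <- cfg$noise %||% list()
  ins <- cfg$instrument %||% list()
  grid_from <- function(g, default, unit) {
    if (is.null(g)) default else axis_grid(seq(g$from, g$to, by = g$step), unit)
  }
  instrument <- fusion_instrument(
    drift_grid = grid_from(ins$drift_time_ms, axis_grid(seq(4, 16, by = 0.1), "ms"), "ms"),
    wavelength_grid = grid_from(ins$wavelength_um,
                                axis_grid(seq(7.4, 10.7, by = 0.01), "um"), "um"),
    time_grid = grid_from(ins$chromatogram_s, axis_grid(seq(0, 180, by = 0.5), "s"), "s"),
    calibration = mobility_calibration(
      ins$calibration$reference_peak_K0 %||% 2.45,
      ins$calibration$reference_drift_time_ms %||% 8.0),
    rip_amplitude = ins$rip_amplitude_nA %||% 8,
    peak_width = ins$peak_width_ms %||% 0.25,
    amplitude_max = ins$amplitude_max_nA %||% 10,
    saturation_ppb = ins$saturation_ppb %||% 20,
    scans = ins$scans %||% 100,
    spectrum_amplitude = ins$spectrum_amplitude %||% 0.24,
    qepas_floor_ratio = ins$qepas_floor_ratio %||% 0.01,
    qepas_rin_ratio = ins$qepas_rin_ratio %||% 0.75,
    chrom_amplitude = ins$chrom_amplitude %||% 1,
    chrom_width = ins$chrom_width_s %||% 0.8)
  list(analytes = analytes,
       noise = noise_model(nz$baseline_sd %||% 0.002,
                           nz$drift_amplitude %||% 0.15,
                           nz$rt_jitter_sd %||% 0.05),
       instrument = instrument)
}

#' Default analyte templates shipped with the package
#'
#' @return Named list of [analyte_template()]s.
#' @export
default_templates <- function() load_templates()$analytes
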