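# Analyte templates, noise model and instrument constants for the synthetic
# sensor-data generator.
#
# Only TATP's reduced mobility (2.06 cm2 V-1 s-1) is a published constant;
# every other number here is a synthetic fixture chosen to look like field
# data for these instrument classes. The four default training concentrations
# are set in the corpus generator: 2.8 and 5.7 ppb are study values, 50 and
# 500 ppb are stand-ins spanning "higher concentrations".

instrument:
  drift_time_ms:   {from: 4.0, to: 16.0, step: 0.1}
  wavelength_um:   {from: 7.4, to: 10.7, step: 0.01}
  chromatogram_s:  {from: 0.0, to: 180.0, step: 0.5}
  calibration:     {reference_peak_K0: 2.45, reference_drift_time_ms: 8.0}
  rip_amplitude_nA: 8.0
  peak_width_ms: 0.25
  amplitude_max_nA: 10.0
  saturation_ppb: 20.0
  scans: 100
  spectrum_amplitude: 0.24
  qepas_floor_ratio: 0.01
  qepas_rin_ratio: 0.75
  chrom_amplitude: 1.0
  chrom_width_s: 0.8

noise:
  baseline_sd: 0.002
  drift_amplitude: 0.15
  rt_jitter_sd: 0.05

analytes:
  acetone:
    ims_peaks:
      - {reduced_mobility: 1.90, relative_amplitude: 1.0, min_concentration: 0.0}
    rt_mean: 45.0
    rt_sd: 0.05
    ir_bands:
      - {center: 8.22, width: 0.12, relative_amplitude: 1.0}
      - {center: 9.17, width: 0.15, relative_amplitude: 0.55}
  dmmp:
    ims_peaks:
      - {reduced_mobility: 1.81, relative_amplitude: 1.0, min_concentration: 0.0}
      # secondary peak appears only at high concentration (gate is a stand-in)
      - {reduced_mobility: 1.43, relative_amplitude: 0.45, min_concentration: 50.0}
    rt_mean: 95.0
    rt_sd: 0.05
    ir_bands:
      - {center: 7.93, width: 0.12, relative_amplitude: 1.0}
      - {center: 9.52, width: 0.15, relative_amplitude: 0.70}
      - {center: 10.35, width: 0.20, relative_amplitude: 0.30}
  tatp:
    ims_peaks:
      - {reduced_mobility: 2.06, relative_amplitude: 1.0, min_concentration: 0.0}
    rt_mean: 70.0
    rt_sd: 0.05
    ir_bands:
      - {center: 8.52, width: 0.12, relative_amplitude: 1.0}
      - {center: 9.90, width: 0.15, relative_amplitude: 0.60}
      - {center: 7.62, width: 0.10, relative_amplitude: 0.40}
  # confuser compound for false-positive checks
  toluene:
    ims_peaks:
      - {reduced_mobility: 1.70, relative_amplitude: 0.8, min_concentration: 0.0}
    rt_mean: 55.0
    rt_sd: 0.05
    ir_bands:
      - {center: 10.10, width: 0.12, relative_amplitude: 1.0}
      - {center: 7.52, width: 0.08, relative_amplitude: 0.45}
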