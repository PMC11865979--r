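Package: chemfuse
Title: Multi-Level Sensor Data Fusion for On-Site Chemical Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fusing ion mobility spectrometry (IMS) plasmagrams with
    gas chromatography / quartz-enhanced photoacoustic spectroscopy (GC-QEPAS)
    retention times and infrared spectra to identify hazardous compounds
    (acetone, DMMP, TATP) in the field. Implements low-, mid- and high-level
    data fusion: concatenated preprocessed blocks or per-block PCA scores
    classified by a one-class support vector machine with analyte-specific
    decision-function thresholds, and a decision-level combination of a
    one-class IMS verdict with a SIMCA (class-wise PCA score distance)
    GC-QEPAS verdict. Includes a spatial co-location gate with
    measurement-error budgets that decides when two sensors' readings may be
    fused, single-sensor identification baselines (reduced-mobility matching,
    retention-time windows, Pearson spectral matching, LDA), a seeded
    synthetic-data generator for all three sensor channels, and stratified
    k-fold evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    withr
Config/testthat/edition: 3
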