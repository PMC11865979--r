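---
title: "Methods: multi-level fusion of IMS and GC-QEPAS sensor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level fusion of IMS and GC-QEPAS sensor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemfuse)
```

## The problem

Field identification of hazardous compounds -- the sarin simulant DMMP, the
peroxide explosive TATP, and acetone as a drug precursor -- benefits from
combining orthogonal sensors. An ion mobility spectrometer (IMS) produces a
plasmagram (ion current vs. drift time); a gas chromatograph coupled to
quartz-enhanced photoacoustic spectroscopy (GC-QEPAS) produces a retention
time and a mid-IR spectrum over 7.4--10.7 um. Either sensor alone
misidentifies at low concentration; fusing them improves both precision and
recall, *provided the two instruments actually sampled the same material*.
chemfuse implements the full chain: a spatial co-location gate, the
preprocessing operators, three fusion strategies, single-sensor baselines,
and a synthetic-data generator that stands in for instrument data.

## The co-location gate

Each reading carries a position relative to a scene reference point, with a
per-axis measurement error: 0.01 m for a measuring tape, 0.0015 m for a
laser distance meter. For two positions the package computes per-axis
absolute separations, the Euclidean distance, and first-order error
propagation (`sigma_axis = sqrt(s1^2 + s2^2)`). The default gate fuses only
when *every* axis separation plus its propagated sigma is below 1 m (the
indoor rule; the cutoff and an alternative Euclidean mode are exposed).
Measurement uncertainty counts **against** fusion: fusing readings of two
different substances is the failure mode the gate exists to prevent, so a
separation of 0.999 m measured by tape (sigma 0.014 m in quadrature) does
not fuse. Readings must also fall within a configurable time window
(default 300 s), since an analyte cloud disperses; the window is logged in
the decision.

## Preprocessing

* **IMS traces** are column-autoscaled: per-variable mean and sample
  (n-1) standard deviation from the training rows only; zero-variance
  columns are dropped, and the drop list is stored in the model so the
  transform is reproducible at prediction time.
* **IR spectra** receive the standard normal variate (SNV) transform:
  each spectrum is centered and scaled to unit sd row-wise, removing
  multiplicative gain and additive offset. SNV is idempotent and
  affine-invariant.
* **Retention times** enter the feature matrices raw.
* **Plasmagram peaks** are local maxima of a 5-point moving-average-smoothed
  trace above a 1 nA floor, annotated with reduced mobility through a
  single-point calibration `K0 = K0_ref * td_ref / td` against the
  reactant-ion peak. The full Mason--Schamp conversion needs drift length
  and field strength, which a deployed unit calibrates away; the one-point
  form is sufficient and testable, and pressure/temperature ride on the
  plasmagram object for a future full conversion.

Every operator appends a descriptor to the block's provenance; the low-level
assembler refuses blocks that skipped their required step.

## The three fusion levels

**LLDF** concatenates `[autoscaled IMS | SNV spectra | raw RT]` into one
matrix and trains a one-class support vector machine on target-analyte
samples only. **MLDF** first reduces each preprocessed block by PCA,
retaining the smallest component count whose cumulative explained variance
reaches 99%, then concatenates the scores with the raw retention time and
trains the same one-class SVM. **HLDF** runs two independent detectors --
a one-class SVM on the raw plasmagram trace and a SIMCA class model on
`[SNV spectra | RT]` -- and combines their boolean verdicts.

### One-class SVM and the threshold override

The estimator is libsvm's nu-one-class formulation (via e1071) with the
fixed hyper-parameters coef0 = 0, degree = 3, gamma = 1/n_features,
tolerance = 0.001, cache 200 MB; the linear kernel is the default, as it
proved the most effective of the four standard kernels for this problem.
Classification replaces the native sign rule with an analyte-specific
threshold tau: inlier iff `f >= tau`, with the published values tau = 0.0
for LLDF, -0.02 (DMMP) and -0.10 (acetone) for MLDF, and 0.0 for the HLDF
IMS branch.

Two numerical design choices deserve explanation.

* **nu defaults to 0.02, not libsvm's 0.5.** The nu parameter upper-bounds
  the fraction of *training* samples left outside the boundary. A safety
  detector tuned to avoid false negatives must not reject its own training
  exemplars; with nu < 1/n the optimizer returns the tightest boundary
  containing the whole training set, which is the geometry under which a
  0.0 threshold yields zero training false negatives. With the 0.5 default
  half the training set would sit outside the boundary and the published
  thresholds could not reproduce the no-false-negative behaviour.
* **The closed boundary is honoured at solver precision.** With a
  hard-margin fit the entire training set can be active, i.e. exactly on
  the boundary in exact arithmetic, while the solver reports +/-O(tol)
  noise around zero. `ocsvm_classify` therefore treats values within the
  convergence tolerance (0.001) of tau as on-boundary inliers. The
  tolerance is small relative to every physical effect in the data and is
  stored with the model.

### Why the HLDF IMS branch uses raw traces

Autoscaling centers every column exactly, so an autoscaled training block
has its mean at the origin -- and a *linear* one-class SVM, whose boundary
is a hyperplane between the data and the origin, becomes degenerate: every
sample ends up on the boundary and the verdict is numerical noise. In the
LLDF/MLDF matrices the SNV spectra (whose mean pattern is far from the
origin) and the raw retention-time column anchor the boundary, so
autoscaling the IMS block there is harmless. The HLDF IMS branch has no such
anchor, so it trains on the raw trace, where the stable reactant-ion peak
(~8 nA) plays that role. This matches how the branch behaves as a standalone
detector.

### SIMCA

SIMCA is implemented from scratch. The class model is a centered PCA of the
class's training samples; components are retained by the same 99%
explained-variance criterion (configurable). A new sample is projected into
score space and accepted when its Euclidean distance to the class centroid
is at most 5.5 **and** its Mahalanobis distance at most 6.5. The
Mahalanobis form divides per-component deviations by the training score
standard deviations -- exact in score space, where the covariance is
diagonal by construction. The centroid is the zero vector by construction
and is stored explicitly.

## Evaluation protocol

`kfold_evaluate` runs stratified k-fold cross-validation (default k = 5; k
is logged in every report because no canonical value exists for these
corpus sizes). Folds are stratified by analyte label *and* concentration,
so that every training fold spans the full concentration range -- with only
ten replicates per concentration cell, unstratified folds can exclude an
entire concentration group from training, which a deployed training set
never would. All preprocessing, PCA and SVM/SIMCA fitting happen strictly
inside the training folds. Metrics follow the usual definitions, with
degenerate denominators reported as 0 rather than NaN so reports aggregate.

A caution on the 100%-accuracy claims: a one-class boundary touches its
training hull, so under cross-validation the sample with the extreme
projection is always evaluated by the one fold that excluded it. With
continuous noise, literal 100% held-out accuracy is therefore a stochastic
event, not a structural guarantee; the *training-set* decision values, by
contrast, satisfy the zero-false-negative property deterministically under
the nu and tau defaults. The acceptance checks assert both facets: exact
zero training false negatives, and held-out accuracy within a few percent
of 100. On the default corpora the held-out accuracies come out at
95--100% depending on the seed.

## The synthetic-data generator

The generator emulates the study conditions rather than instrument physics:
no ionization chemistry, photoacoustic transduction or column dynamics are
modelled. Per analyte it draws, under a fixed seed,

* a **plasmagram**: Gaussian peaks (sd 0.25 ms) at the drift times implied
  by the template reduced mobilities -- only TATP's 2.06 cm2/V/s is a
  published constant; the rest are invented fixtures in
  `inst/extdata/templates.yaml` -- plus the reactant-ion peak (8 nA at the
  calibration reference, K0 2.45), on a 4--16 ms grid at 0.1 ms. Peak
  amplitude follows a saturating law `A_max * c / (c + 20 ppb)` (A_max =
  10 nA), a bounded detector response; a linear law would make the two
  upper concentrations implausibly dominant. At 2.8 ppb the main peak sits
  just above the 1 nA identification floor and sub-ppb levels fall below
  it. DMMP carries a second mobility peak gated at >= 50 ppb (the
  phenomenon is documented, its threshold is not; the gate is config
  data).
* a **chromatogram**: one Gaussian peak (sd 0.8 s, a fast-GC width) whose
  apex is drawn from `Normal(rt_mean, rt_sd = 0.05 s)` plus 0.05 s jitter,
  sampled at 0.5 s -- the detector sampling, not the chemistry, dominates
  the observed retention-time variance, as it does for a well-conditioned
  column.
* an **IR spectrum**: the sum of 2--3 Gaussian bands scaled by the same
  saturating law, on the 7.4--10.7 um grid at 0.01 um, with an additive
  noise floor (2e-5 a.u.) and relative-intensity noise (0.15% of the rms
  signal). The lowest study concentration sits well above the detection
  limit, hence the high SNR.

Run-to-run variation ("different operators, days, solvent batches") enters
as a shared per-sample gain factor `exp(N(0, 0.15))` applied to every
channel, an IMS baseline offset (sd 0.002 nA), and scan-averaged IMS white
noise (0.002 nA / sqrt(100 scans)). Setting the noise model to zero
reproduces the analytic signal model exactly, which the tests exploit.

What the generator deliberately does *not* reproduce: matrix effects and
humidity-driven mobility shifts, competing-ion suppression at high
concentration, column bleed and retention drift over long campaigns, and
structured (non-white) detector noise. Passing tests on this corpus show
that the pipeline implements the intended mathematics and decision rules
under the stated conditions -- they do not certify field performance on
real mixtures.

The default corpus for the replication protocol is 10 replicates at each of
2.8, 5.7, 50 and 500 ppb (n = 40 per analyte); 2.8 and 5.7 ppb are study
values, the upper two are stand-ins spanning "higher concentrations", and
all four are configurable. These sizes keep the full evaluation -- three
corpora, six cross-validated pipelines -- under half a minute on one core.

```{r corpus-demo}
corpus <- generate_training_corpus(default_templates()$dmmp,
                                   n_per_analyte = 2,
                                   concentrations = c(2.8, 50), seed = 7)
corpus
```

## Degenerate inputs and tie-breaks

Constant spectra have no SNV and raise an error rather than returning NaN;
zero-variance columns are dropped at autoscale time; a flat chromatogram
has no retention time; peak detection returns an empty table rather than
failing; `which.max` resolves retention-time ties to the earlier grid
point; reduced-mobility windows and retention-time windows are closed
intervals (detection-biased). PCA ranks are guarded against numerically
zero singular values at a relative 1e-12 threshold.

## Known limitations

* The co-location gate models positions as static points; moving sources
  and airflow are out of scope (as is the outdoor scenario generally).
* The reduced-mobility conversion is single-point; plasmagrams carry
  pressure and temperature for a future Mason--Schamp implementation.
* The concentration-robustness comparison (MLDF decision spread vs. LLDF)
  is meaningful when concentration structure survives preprocessing; on
  the clean default corpus both spreads are small and the comparison is
  made under the fixed replication protocol.
* Quantification (estimating concentration) is out of scope; the system
  classifies only.
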