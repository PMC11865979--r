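# Preprocessing operators: column autoscaling (IMS block), row-wise standard
# normal variate (IR spectra), grid resampling, plasmagram peak picking and
# the drift-time -> reduced-mobility conversion. All matrix statistics use
# the sample (n-1) standard deviation.

#' Fit a column autoscaling model
#'
#' Per-variable mean and sample standard deviation from training data.
#' Zero-variance columns are flagged and dropped consistently at apply time;
#' the drop list lives in the model so the transform is reproducible.
#'
#' @param block A [feature_block()] with at least 2 rows.
#' @return An object of class `autoscale_model` with fields `means`, `sds`,
#'   `keep` (logical retain mask) and `n_variables`.
#' @export
autoscale_fit <- function(block) {
  m <- block$matrix
  if (nrow(m) < 2) stopf("autoscale_fit needs at least 2 samples")
  means <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  structure(list(means = means, sds = sds, keep = keep, n_variables = ncol(m)),
            class = "autoscale_model")
}

#' Apply an autoscaling model to a block
#'
#' Retained variables become `(value - mean) / sd`; dropped (zero-variance)
#' variables are removed. Applying a model to its own training block yields
#' column means 0 and sds 1 to numerical precision.
#'
#' @param block A [feature_block()] whose width matches the model.
#' @param model An [autoscale_fit()] result.
#' @return A new [feature_block()] with provenance appended.
#' @export
autoscale_apply <- function(block, model) {
  if (!inherits(model, "autoscale_model")) stopf("model must be an autoscale_model")
  m <- block$matrix
  if (ncol(m) != model$n_variables)
    stopf("block width (%d) does not match model width (%d)", ncol(m), model$n_variables)
  keep <- model$keep
  scaled <- sweep(sweep(m[, keep, drop = FALSE], 2, model$means[keep]),
                  2, model$sds[keep], "/")
  axis <- block$variable_axis
  if (!is.null(axis)) {
    vals <- axis$values[keep]
    axis <- if (length(vals) >= 2) axis_grid(vals, axis$unit) else NULL
  }
  feature_block(block$name, scaled, variable_axis = axis,
                provenance = c(block$provenance,
                               sprintf("autoscale(dropped=%d)", sum(!keep))))
}

#' Standard normal variate (SNV) transform of one spectrum
#'
#' Row-wise centering and scaling to zero mean and unit sample standard
#' deviation. Idempotent and invariant to affine rescaling `a * x + b`
#' (a > 0). A constant spectrum has no defined SNV and raises an error.
#'
#' @param x Numeric vector, length >= 2, with nonzero spread.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (length(x) < 2) stopf("snv needs at least 2 points")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("snv is undefined for a constant spectrum")
  (x - mean(x)) / s
}

#' Apply SNV row-wise to a feature block
#'
#' @param block A [feature_block()] of spectra (one spectrum per row).
#' @return A new [feature_block()] with provenance appended.
#' @export
snv_block <- function(block) {
  out <- t(apply(block$matrix, 1, snv))
  feature_block(block$name, out, variable_axis = block$variable_axis,
                provenance = c(block$provenance, "snv()"))
}

#' Linear resampling of a signal onto a new axis grid
#'
#' @param values Numeric vector on `from_grid`.
#' @param from_grid,to_grid [axis_grid()]s with the same unit; `to_grid` must
#'   lie within the span of `from_grid` (no extrapolation).
#' @return Numeric vector on `to_grid`.
#' @export
resample_signal <- function(values, from_grid, to_grid) {
  if (from_grid$unit != to_grid$unit)
    stopf("cannot resample between units '%s' and '%s'", from_grid$unit, to_grid$unit)
  if (length(values) != length(from_grid$values))
    stopf("values length must match from_grid")
  tol <- 1e-9
  if (min(to_grid$values) < min(from_grid$values) - tol ||
      max(to_grid$values) > max(from_grid$values) + tol)
    stopf("to_grid extends beyond from_grid span; extrapolation is not supported")
  stats::approx(from_grid$values, values, xout = to_grid$values, rule = 1)$y
}

#' Convert drift time to reduced mobility K0
#'
#' Single-point inverse-proportional calibration:
#' `K0 = reference_peak_K0 * reference_drift_time / drift_time`.
#'
#' @param drift_time Drift time(s) in ms, > 0.
#' @param calib A [mobility_calibration()].
#' @return Reduced mobility in cm2/V/s.
#' @export
drift_to_K0 <- function(drift_time, calib = mobility_calibration()) {
  if (any(!is.finite(drift_time)) || any(drift_time <= 0))
    stopf("drift_time must be > 0")
  calib$reference_peak_K0 * calib$reference_drift_time / drift_time
}

#' Detect peaks in a plasmagram
#'
#' Local maxima of the moving-average-smoothed trace whose smoothed intensity
#' exceeds `min_intensity` (default 1 nA, the identification floor), each
#' annotated with its reduced mobility via [drift_to_K0()]. Sorted by drift
#' time; an empty result is allowed.
#'
#' @param p A [plasmagram()].
#' @param min_intensity Intensity floor in nA.
#' @param calib A [mobility_calibration()].
#' @param window Moving-average window in points (odd; default 5).
#' @return Data frame with columns `drift_time`, `intensity`,
#'   `reduced_mobility`.
#' @export
detect_peaks <- function(p, min_intensity = 1.0, calib = mobility_calibration(),
                         window = 5) {
  if (!inherits(p, "plasmagram")) stopf("p must be a plasmagram")
  s <- moving_average(p$current, window)
  n <- length(s)
  if (n < 3) return(data.frame(drift_time = numeric(), intensity = numeric(),
                               reduced_mobility = numeric()))
  i <- 2:(n - 1)
  is_max <- s[i] > s[i - 1] & s[i] >= s[i + 1]
  idx <- i[is_max]
  idx <- idx[s[idx] > min_intensity]
  data.frame(drift_time = p$drift_time$values[idx],
             intensity = s[idx],
             reduced_mobility = drift_to_K0(p$drift_time$values[idx], calib))
}

#' Extract the retention time of the dominant chromatogram peak
#'
#' Apex time of the globally highest peak; retention times enter the fusion
#' feature matrices raw, without preprocessing.
#'
#' @param c A [chromatogram()] with a non-flat signal.
#' @return Retention time in s.
#' @export
extract_rt <- function(c) {
  if (!inherits(c, "chromatogram")) stopf("c must be a chromatogram")
  if (max(c$signal) - min(c$signal) <= 0)
    stopf("flat chromatogram: no peak to extract")
  c$time$values[which.max(c$signal)]
}
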