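# Single-sensor identification baselines: reduced-mobility library matching,
# retention-time windows, Pearson spectral matching, LDA, and the sequential
# RT-then-spectrum GC-QEPAS combination.

#' Reduced-mobility library entry
#'
#' An analyte is identified on the IMS channel when at least `required_peaks`
#' detected peaks exceed `min_intensity` and fall within the multiplicative
#' K0 window `[K0 * (1 - tolerance), K0 * (1 + tolerance)]` of the analyte's
#' library mobilities (2% tolerance and a 1 nA floor by default).
#'
#' @param analyte Analyte name.
#' @param K0 Library reduced mobility (cm2/V/s), > 0.
#' @param tolerance Fractional window half-width, in (0, 1). Default 0.02.
#' @param min_intensity Intensity floor (nA). Default 1.
#' @param required_peaks Number of matching peaks required. Default 1.
#' @return An object of class `rm_library_entry`.
#' @export
rm_library_entry <- function(analyte, K0, tolerance = 0.02, min_intensity = 1.0,
                             required_peaks = 1L) {
  if (!is.finite(K0) || K0 <= 0) stopf("K0 must be > 0")
  if (!is.finite(tolerance) || tolerance <= 0 || tolerance >= 1)
    stopf("tolerance must be in (0, 1)")
  structure(list(analyte = analyte, K0 = K0, tolerance = tolerance,
                 min_intensity = min_intensity,
                 required_peaks = as.integer(required_peaks)),
            class = "rm_library_entry")
}

#' Identify analytes from plasmagram peaks by reduced mobility
#'
#' For each entry, counts peaks above the entry's intensity floor whose K0
#' falls within the window of any library mobility assigned to the same
#' analyte, and reports a match when the count reaches the entry's
#' `required_peaks`.
#'
#' @param peaks Data frame from [detect_peaks()] (columns `intensity`,
#'   `reduced_mobility`).
#' @param library Non-empty list of [rm_library_entry()]s.
#' @return Data frame with columns `analyte`, `matched`, `n_matched`.
#' @export
rm_identify <- function(peaks, library) {
  if (length(library) == 0) stopf("library must be non-empty")
  if (!all(vapply(library, inherits, TRUE, "rm_library_entry")))
    stopf("library must contain rm_library_entry objects")
  analytes <- vapply(library, function(e) e$analyte, "")
  out <- lapply(library, function(e) {
    k0s <- vapply(library[analytes == e$analyte], function(x) x$K0, 0)
    in_window <- function(k) any(k >= k0s * (1 - e$tolerance) &
                                 k <= k0s * (1 + e$tolerance))
    n <- if (nrow(peaks) == 0) 0L else
      sum(peaks$intensity > e$min_intensity &
            vapply(peaks$reduced_mobility, in_window, TRUE))
    data.frame(analyte = e$analyte, matched = n >= e$required_peaks, n_matched = n)
  })
  do.call(rbind, out)
}

#' Retention-time window model
#'
#' Acceptance region of the Gaussian retention-time model, reduced to the
#' symmetric closed interval `mu +/- k * sigma` (k = 3 by default; closed
#' boundaries bias toward detection).
#'
#' @param analyte Analyte name.
#' @param mu,sigma Retention-time mean and sd (s), `sigma > 0`.
#' @param k Window half-width multiplier, > 0.
#' @return An object of class `rt_model`.
#' @export
rt_model <- function(analyte, mu, sigma, k = 3) {
  if (!is.finite(sigma) || sigma <= 0) stopf("sigma must be > 0")
  if (!is.finite(k) || k <= 0) stopf("k must be > 0")
  structure(list(analyte = analyte, mu = mu, sigma = sigma, k = k),
            class = "rt_model")
}

#' Retention-time detection
#'
#' @param rt Observed retention time (s).
#' @param model An [rt_model()].
#' @return `TRUE` iff `|rt - mu| <= k * sigma`.
#' @export
rt_detect <- function(rt, model) {
  if (!inherits(model, "rt_model")) stopf("model must be an rt_model")
  abs(rt - model$mu) <= model$k * model$sigma
}

#' Spectral reference for Pearson matching
#'
#' @param analyte Analyte name.
#' @param spectrum An [ir_spectrum()]; stored SNV-normalized.
#' @param r_min Correlation threshold in [-1, 1]. Default 0.95.
#' @return An object of class `spectral_reference`.
#' @export
spectral_reference <- function(analyte, spectrum, r_min = 0.95) {
  if (!inherits(spectrum, "ir_spectrum")) stopf("spectrum must be an ir_spectrum")
  if (!is.finite(r_min) || r_min < -1 || r_min > 1) stopf("r_min must be in [-1, 1]")
  structure(list(analyte = analyte,
                 wavelength = spectrum$wavelength,
                 signal = snv(spectrum$signal),
                 r_min = r_min),
            class = "spectral_reference")
}

#' Pearson correlation match of a spectrum against a reference
#'
#' Both spectra are SNV-normalized before correlating (SNV is idempotent, so
#' pre-normalized input is fine), which makes the score invariant to affine
#' rescaling of either spectrum. A score near 1 indicates high similarity;
#' near 0, dissimilarity.
#'
#' @param spectrum An [ir_spectrum()] on the reference grid (resample first if
#'   needed; see [resample_signal()]).
#' @param ref A [spectral_reference()].
#' @return List with `r` (Pearson correlation) and `matched`
#'   (`r >= ref$r_min`).
#' @export
pearson_match <- function(spectrum, ref) {
  if (!inherits(ref, "spectral_reference")) stopf("ref must be a spectral_reference")
  if (!inherits(spectrum, "ir_spectrum")) stopf("spectrum must be an ir_spectrum")
  if (!axes_equal(spectrum$wavelength, ref$wavelength))
    stopf("spectrum grid differs from the reference grid; resample first")
  x <- snv(spectrum$signal)  # errors on a constant spectrum
  r <- stats::cor(x, ref$signal)
  list(r = r, matched = r >= ref$r_min)
}

#' Build class-mean spectral references from a labelled dataset
#'
#' @param dataset A [labelled_dataset()] with an IR spectra block.
#' @param block Name of the spectra block. Default `"qepas"`.
#' @param r_min Threshold stored in each reference.
#' @return Named list of [spectral_reference()]s, one per label.
#' @export
build_spectral_references <- function(dataset, block = "qepas", r_min = 0.95) {
  b <- dataset$blocks[[block]]
  if (is.null(b)) stopf("dataset has no block '%s'", block)
  axis <- b$variable_axis
  if (is.null(axis)) stopf("block '%s' carries no wavelength axis", block)
  refs <- lapply(unique(dataset$labels), function(lb) {
    m <- b$matrix[dataset$labels == lb, , drop = FALSE]
    mean_snv <- colMeans(t(apply(m, 1, snv)))
    spectral_reference(lb, ir_spectrum(axis, mean_snv,
                                       range = range(axis$values)),
                       r_min = r_min)
  })
  names(refs) <- unique(dataset$labels)
  refs
}

#' Fit a multiclass LDA baseline
#'
#' Standard linear discriminant analysis on the concatenation of the named
#' blocks, used only as a comparison baseline against the fusion strategies.
#' For wide blocks (more variables than samples) set `pca_dims` to project
#' onto leading principal components first; a singular within-class scatter
#' otherwise raises an error advising exactly that.
#'
#' @param dataset A [labelled_dataset()] with >= 2 classes of >= 2 samples.
#' @param blocks Character vector of block names to concatenate.
#' @param pca_dims Optional number of PCA dimensions to reduce to before LDA.
#' @return An object of class `lda_baseline`.
#' @export
lda_fit <- function(dataset, blocks = names(dataset$blocks), pca_dims = NULL) {
  labs <- factor(dataset$labels)
  if (nlevels(labs) < 2) stopf("LDA needs at least 2 classes")
  if (any(table(labs) < 2)) stopf("every class needs at least 2 samples")
  missing <- setdiff(blocks, names(dataset$blocks))
  if (length(missing)) stopf("unknown blocks: %s", paste(missing, collapse = ", "))
  x <- do.call(cbind, lapply(dataset$blocks[blocks], function(b) b$matrix))
  proj <- NULL
  if (!is.null(pca_dims)) {
    pr <- stats::prcomp(x, center = TRUE)
    k <- min(pca_dims, ncol(pr$rotation))
    proj <- list(center = pr$center, rotation = pr$rotation[, seq_len(k), drop = FALSE])
    x <- pr$x[, seq_len(k), drop = FALSE]
  }
  fit <- tryCatch(
    suppressWarnings(MASS::lda(x, grouping = labs)),
    error = function(e) stopf(paste("LDA failed (%s); the within-class scatter is",
                                    "likely singular -- reduce with pca_dims first"),
                              conditionMessage(e)))
  structure(list(fit = fit, blocks = blocks, proj = proj), class = "lda_baseline")
}

#' Predict analyte labels with a fitted LDA baseline
#'
#' @param model An [lda_fit()] result.
#' @param newdata A [labelled_dataset()] sharing the training blocks, or a
#'   numeric matrix already in the concatenated feature order.
#' @return Character vector of predicted labels.
#' @export
lda_predict <- function(model, newdata) {
  x <- if (inherits(newdata, "labelled_dataset")) {
    do.call(cbind, lapply(newdata$blocks[model$blocks], function(b) b$matrix))
  } else newdata
  if (!is.null(model$proj))
    x <- sweep(x, 2, model$proj$center) %*% model$proj$rotation
  as.character(stats::predict(model$fit, x)$class)
}

#' Sequential GC-QEPAS identification: RT window then spectral confirmation
#'
#' The retention-time window screens; the Pearson spectral match confirms. An
#' analyte is matched only when both pass (sequential AND).
#'
#' @param rt Observed retention time (s).
#' @param spectrum An [ir_spectrum()] on the reference grid.
#' @param rt_models Named list of [rt_model()]s.
#' @param references Named list of [spectral_reference()]s over the same
#'   analyte name-space.
#' @return Data frame with columns `analyte`, `rt_ok`, `r`, `matched`.
#' @export
gcqepas_sequential_id <- function(rt, spectrum, rt_models, references) {
  a1 <- sort(vapply(rt_models, function(m) m$analyte, ""))
  a2 <- sort(vapply(references, function(r) r$analyte, ""))
  if (!identical(a1, a2))
    stopf("rt_models and references must cover the same analytes")
  out <- lapply(rt_models, function(m) {
    ref <- references[[which(vapply(references, function(r) r$analyte, "") == m$analyte)[1]]]
    rt_ok <- rt_detect(rt, m)
    pm <- pearson_match(spectrum, ref)
    data.frame(analyte = m$analyte, rt_ok = rt_ok, r = pm$r,
               matched = rt_ok && pm$matched)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
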