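# Multi-block assembly for the three fusion levels.
#
# LLDF: column-wise concatenation [autoscaled IMS | SNV IR spectra | raw RT].
# MLDF: per-block PCA scores (components retained up to >= 99% cumulative
# explained variance, fitted on training data only) concatenated with raw RT.
# HLDF: decision-level combination of the per-sensor verdicts.

#' Assemble the low-level fusion feature matrix
#'
#' Concatenates the preprocessed blocks into one matrix in the fixed,
#' documented column order: autoscaled IMS trace, SNV IR spectrum, raw
#' retention time (one trailing column). Provenance is enforced: the IMS
#' block must record an `autoscale` step and the spectra block an `snv` step.
#'
#' @param ims_block Autoscaled [feature_block()].
#' @param qepas_block SNV-transformed [feature_block()].
#' @param rt Numeric vector of retention times (s), one per row, used raw.
#' @return A [feature_block()] named `"lldf"`.
#' @export
lldf_assemble <- function(ims_block, qepas_block, rt) {
  if (!any(grepl("^autoscale", ims_block$provenance)))
    stopf("IMS block has no autoscale step in its provenance; run autoscale_apply first")
  if (!any(grepl("^snv", qepas_block$provenance)))
    stopf("spectra block has no snv step in its provenance; run snv_block first")
  n <- nrow(ims_block$matrix)
  if (nrow(qepas_block$matrix) != n || length(rt) != n)
    stopf("row counts differ: ims %d, qepas %d, rt %d",
          n, nrow(qepas_block$matrix), length(rt))
  m <- cbind(ims_block$matrix, qepas_block$matrix, rt = as.numeric(rt))
  feature_block("lldf", m,
                provenance = c(paste0("ims:", ims_block$provenance),
                               paste0("qepas:", qepas_block$provenance),
                               "rt:raw"))
}

#' Fit per-block PCA models at an explained-variance criterion
#'
#' Each block gets its own centered PCA; the retained component count is the
#' smallest reaching the cumulative explained-variance criterion.
#'
#' @param blocks Named list of [feature_block()]s (training data only).
#' @param ev Cumulative explained-variance criterion. Default 0.99.
#' @return An object of class `pca_block_model`.
#' @export
pca_blocks_fit <- function(blocks, ev = 0.99) {
  fits <- lapply(blocks, function(b) {
    x <- b$matrix
    check_finite_matrix(x, sprintf("block '%s'", b$name))
    center <- colMeans(x)
    sv <- svd(sweep(x, 2, center))
    var_frac <- sv$d^2 / sum(sv$d^2)
    rank <- sum(sv$d > max(sv$d) * 1e-12)
    m <- min(which(cumsum(var_frac) >= ev - 1e-12), rank)
    list(center = center, loadings = sv$v[, seq_len(m), drop = FALSE],
         n_components = m, explained_variance = var_frac,
         n_features = ncol(x))
  })
  structure(list(fits = fits, ev = ev), class = "pca_block_model")
}

pca_block_scores <- function(model, name, x) {
  f <- model$fits[[name]]
  if (is.null(f)) stopf("PCA model has no block '%s'", name)
  if (ncol(x) != f$n_features)
    stopf("block '%s' width (%d) does not match PCA model width (%d)",
          name, ncol(x), f$n_features)
  sweep(x, 2, f$center) %*% f$loadings
}

#' Assemble the mid-level fusion feature matrix
#'
#' Per-block PCA scores of the (preprocessed) IMS and spectra blocks,
#' concatenated with the raw retention time.
#'
#' @param ims_block,qepas_block Preprocessed [feature_block()]s.
#' @param rt Numeric vector of retention times, one per row.
#' @param pca A [pca_blocks_fit()] model fitted on training data only, with
#'   blocks named `ims` and `qepas`.
#' @return A [feature_block()] named `"mldf"`.
#' @export
mldf_assemble <- function(ims_block, qepas_block, rt, pca) {
  if (!inherits(pca, "pca_block_model")) stopf("pca must be a pca_block_model")
  n <- nrow(ims_block$matrix)
  if (nrow(qepas_block$matrix) != n || length(rt) != n)
    stopf("row counts differ across blocks")
  m <- cbind(pca_block_scores(pca, "ims", ims_block$matrix),
             pca_block_scores(pca, "qepas", qepas_block$matrix),
             rt = as.numeric(rt))
  feature_block("mldf", m,
                provenance = c(sprintf("pca(ims, %d comps)", pca$fits$ims$n_components),
                               sprintf("pca(qepas, %d comps)", pca$fits$qepas$n_components),
                               "rt:raw"))
}

#' Combine per-sensor verdicts at the decision level (HLDF)
#'
#' @param ims One-row result of [ocsvm_classify()] (fields `f`, `inlier`), or
#'   a list with those fields.
#' @param gc One-row result of [simca_classify()] (fields `dE`, `dM`,
#'   `positive`), or a list with those fields.
#' @param rule `"any"` (default; safety alarm -- positive if either sensor is
#'   positive) or `"all"` (confirmation -- positive only if both are).
#' @return List with `positive`, `rule`, `ims`, `gc`.
#' @export
hldf_combine <- function(ims, gc, rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (is.null(ims) || is.null(ims$inlier)) stopf("missing IMS verdict")
  if (is.null(gc) || is.null(gc$positive)) stopf("missing GC-QEPAS verdict")
  ims_pos <- isTRUE(as.logical(ims$inlier)[1])
  gc_pos <- isTRUE(as.logical(gc$positive)[1])
  positive <- if (rule == "any") ims_pos || gc_pos else ims_pos && gc_pos
  list(positive = positive, rule = rule,
       ims = as.list(ims[1, , drop = FALSE]),
       gc = as.list(gc[1, , drop = FALSE]))
}
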