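# SIMCA: soft independent modelling of class analogy, implemented from
# scratch. One PCA model per class; a new sample is accepted when its
# score-space Euclidean and Mahalanobis distances to the class centroid both
# fall below fixed limits. The Mahalanobis form uses per-component training
# score standard deviations, which is exact in PCA score space (diagonal
# covariance by construction).

#' Fit a SIMCA class model
#'
#' Class-wise PCA on (already preprocessed) training samples of one class.
#' Components are retained up to the smallest count reaching the cumulative
#' explained-variance criterion (99% by default, as for the mid-level fusion
#' PCA), or a fixed `ncomp`. The centroid is the zero score vector by
#' construction of the centered PCA and is stored explicitly.
#'
#' @param x Numeric matrix or [feature_block()], >= 3 rows of one class.
#' @param label Class label stored with the model.
#' @param ncomp Fixed number of components (optional).
#' @param ev Cumulative explained-variance criterion used when `ncomp` is
#'   `NULL`. Default 0.99.
#' @param dE_max Euclidean distance limit. Default 5.5.
#' @param dM_max Mahalanobis distance limit. Default 6.5.
#' @return An object of class `simca_model` with fields `center`, `loadings`
#'   (orthonormal columns), `score_sd`, `centroid`, `explained_variance`,
#'   `dE_max`, `dM_max`, `label`.
#' @export
simca_fit <- function(x, label = NULL, ncomp = NULL, ev = 0.99,
                      dE_max = 5.5, dM_max = 6.5) {
  if (inherits(x, "feature_block")) x <- x$matrix
  check_finite_matrix(x, "SIMCA training data")
  n <- nrow(x)
  if (n < 3) stopf("SIMCA needs at least 3 samples of the class")
  if (dE_max <= 0 || dM_max <= 0) stopf("distance limits must be > 0")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc)
  var_frac <- sv$d^2 / sum(sv$d^2)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  m <- if (!is.null(ncomp)) {
    if (ncomp > rank) stopf("requested %d components but rank is %d", ncomp, rank)
    as.integer(ncomp)
  } else {
    min(which(cumsum(var_frac) >= ev - 1e-12), rank)
  }
  loadings <- sv$v[, seq_len(m), drop = FALSE]
  scores <- xc %*% loadings
  score_sd <- apply(scores, 2, stats::sd)
  if (any(score_sd <= 0)) stopf("retained components must have positive score sd")
  structure(list(label = label, center = center, loadings = loadings,
                 score_sd = score_sd, centroid = rep(0, m),
                 explained_variance = var_frac[seq_len(m)],
                 n_components = m, n_features = ncol(x),
                 dE_max = dE_max, dM_max = dM_max),
            class = "simca_model")
}

#' Classify samples against a SIMCA class model
#'
#' Projects each sample into the class score space and computes
#' `dE = sqrt(sum((t - c)^2))` and `dM = sqrt(sum(((t - c) / s)^2))` against
#' the class centroid `c` and training score sds `s`. Positive iff
#' `dE <= dE_max` and `dM <= dM_max`.
#'
#' @param model A [simca_fit()] result.
#' @param x Numeric matrix (rows = samples) or [feature_block()], preprocessed
#'   identically to the training data.
#' @param dE_max,dM_max Optional overrides of the stored limits.
#' @return Data frame with columns `dE`, `dM`, `positive`.
#' @export
simca_classify <- function(model, x, dE_max = model$dE_max,
                           dM_max = model$dM_max) {
  if (!inherits(model, "simca_model")) stopf("model must be a simca_model")
  if (inherits(x, "feature_block")) x <- x$matrix
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  check_finite_matrix(x, "features")
  if (ncol(x) != model$n_features)
    stopf("feature width (%d) does not match training width (%d)",
          ncol(x), model$n_features)
  scores <- sweep(x, 2, model$center) %*% model$loadings
  dev <- sweep(scores, 2, model$centroid)
  dE <- sqrt(rowSums(dev^2))
  dM <- sqrt(rowSums(sweep(dev, 2, model$score_sd, "/")^2))
  data.frame(dE = dE, dM = dM, positive = dE <= dE_max & dM <= dM_max)
}
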