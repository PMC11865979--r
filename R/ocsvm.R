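# One-class SVM novelty detector with decision-threshold override.
#
# The estimator itself is libsvm (via e1071); this module's contract is the
# kernel choice, the fixed hyper-parameters (coef0 = 0, degree = 3,
# gamma = 1/n_features, tol = 0.001, cache = 200 MB) and the tau-override
# semantics: a sample is an inlier when its decision-function value f
# satisfies f >= tau, replacing the native sign rule. The closed boundary is
# honoured at solver precision: values within the convergence tolerance of
# tau count as on-boundary inliers, because a hard-margin one-class fit can
# leave the entire training set active with f = 0 in exact arithmetic while
# the solver reports +/-O(tol) noise around it.

map_kernel <- function(kernel) {
  switch(kernel,
         linear = "linear",
         rbf = , radial = "radial",
         poly = , polynomial = "polynomial",
         sigmoid = "sigmoid",
         stopf("unknown kernel '%s'", kernel))
}

#' Fit a one-class SVM on target-class training data
#'
#' @param x Numeric matrix or [feature_block()] of training samples (all from
#'   the target class), >= 2 rows, finite.
#' @param kernel `"linear"` (default), `"rbf"`/`"radial"`,
#'   `"poly"`/`"polynomial"`, or `"sigmoid"`.
#' @param nu Upper bound on the training outlier fraction. Default 0.02: a
#'   safety detector must not reject its own training exemplars, so the
#'   default keeps `nu * n < 1` (hard margin) for the corpus sizes used here.
#' @param threshold Decision threshold tau stored with the model. Default 0
#'   (the low-level fusion setting); mid-level fusion uses analyte-specific
#'   negative values.
#' @param degree,coef0 Polynomial/sigmoid kernel parameters.
#' @param gamma Kernel coefficient; `NULL` (default) uses `1 / n_features`.
#' @param tol Solver convergence tolerance. Default 0.001.
#' @param cache Kernel cache in MB. Default 200.
#' @return An object of class `ocsvm_model` with the fitted estimator, the
#'   stored threshold and the training decision values.
#' @export
ocsvm_fit <- function(x, kernel = "linear", nu = 0.02, threshold = 0,
                      degree = 3, coef0 = 0, gamma = NULL, tol = 1e-3,
                      cache = 200) {
  if (inherits(x, "feature_block")) x <- x$matrix
  check_finite_matrix(x, "training features")
  if (nrow(x) < 2) stopf("one-class training needs at least 2 rows")
  k <- map_kernel(kernel)
  fit <- e1071::svm(x, y = NULL, type = "one-classification", kernel = k,
                    nu = nu, gamma = gamma %||% (1 / ncol(x)),
                    degree = degree, coef0 = coef0, tolerance = tol,
                    cachesize = cache, scale = FALSE)
  train_f <- as.numeric(attr(stats::predict(fit, x, decision.values = TRUE),
                             "decision.values"))
  structure(list(svm = fit, kernel = kernel, nu = nu, threshold = threshold,
                 tol = tol, n_features = ncol(x), train_decision = train_f),
            class = "ocsvm_model")
}

#' Classify samples with a fitted one-class SVM
#'
#' @param model An [ocsvm_fit()] result.
#' @param x Numeric matrix or [feature_block()] with the training width.
#' @param threshold Override of the stored tau (e.g. `-Inf` accepts
#'   everything).
#' @return Data frame with columns `f` (decision value) and `inlier`
#'   (`f >= threshold`, closed at solver precision).
#' @export
ocsvm_classify <- function(model, x, threshold = model$threshold) {
  if (!inherits(model, "ocsvm_model")) stopf("model must be an ocsvm_model")
  if (inherits(x, "feature_block")) x <- x$matrix
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  check_finite_matrix(x, "features")
  if (ncol(x) != model$n_features)
    stopf("feature width (%d) does not match training width (%d)",
          ncol(x), model$n_features)
  f <- as.numeric(attr(stats::predict(model$svm, x, decision.values = TRUE),
                       "decision.values"))
  data.frame(f = f, inlier = f >= threshold - model$tol)
}
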