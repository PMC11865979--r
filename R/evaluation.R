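# Classification metrics and stratified k-fold evaluation of the fusion
# pipelines.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Nonnegative integer counts; their total must be > 0 for
#'   metric computation.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stopf("confusion counts must be nonnegative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`,
#' `accuracy = (tp+tn)/total`. Degenerate denominators yield 0 (not NaN) with
#' a note, so reports aggregate cleanly.
#'
#' @param counts A [confusion_counts()] with total > 0.
#' @return List with `precision`, `recall`, `f1`, `accuracy` and `note`
#'   (character, possibly empty).
#' @examples
#' m <- classification_metrics(confusion_counts(tp = 13, fn = 3))
#' round(c(m$precision, m$recall, m$f1), 2)  # 1 0.81 0.90
#' @export
classification_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    if (is.list(counts)) counts <- do.call(confusion_counts, counts)
    else stopf("counts must be confusion_counts")
  }
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) stopf("empty confusion counts")
  note <- character()
  div <- function(num, den, what) {
    if (den == 0) { note <<- c(note, sprintf("%s denominator is 0; reported as 0", what)); 0 }
    else num / den
  }
  precision <- div(counts$tp, counts$tp + counts$fp, "precision")
  recall <- div(counts$tp, counts$tp + counts$fn, "recall")
  f1 <- if (precision + recall == 0) {
    note <- c(note, "P + R = 0; F1 reported as 0")
    0
  } else 2 * precision * recall / (precision + recall)
  if (length(note)) message("classification_metrics: ", paste(note, collapse = "; "))
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = (counts$tp + counts$tn) / total, note = note)
}

# Stratified fold assignment: within each stratum, fold ids 1..k are dealt as
# evenly as possible in random order. Deterministic given the seed.
stratified_folds <- function(strata, k, seed) {
  folds <- integer(length(strata))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      folds[idx] <- if (length(idx) <= k) sample(seq_len(k), length(idx))
                    else sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

#' Stratified k-fold evaluation of a fusion pipeline
#'
#' Folds are stratified by analyte label and, where available, concentration,
#' so every training fold sees the full concentration range. All
#' preprocessing, PCA and model fitting happen inside the training folds;
#' the held-out rows are classified with the fold's pipeline and the
#' confusion is aggregated over folds. For a single-analyte one-class corpus
#' the relevant errors are false negatives and accuracy equals the inlier
#' rate. Deterministic given the seed.
#'
#' @param dataset A [labelled_dataset()] with blocks `ims`, `qepas`, `rt`.
#' @param level,analyte,... Passed to [train_pipeline()].
#' @param k Number of folds, >= 2 (use `k = n` for leave-one-out). Default 5.
#' @param seed Integer seed controlling fold assignment.
#' @param branch For `level = "hldf"`: evaluate the `"combined"` decision
#'   (default), the `"ims"` one-class branch, or the `"gc"` SIMCA branch.
#' @return An object of class `metrics_report`: confusion counts, metrics,
#'   fold assignment, per-row decisions (with concentrations, for
#'   robustness analysis), `k` and `seed`.
#' @export
kfold_evaluate <- function(dataset, level, analyte, k = 5, seed = 1,
                           branch = c("combined", "ims", "gc"), ...) {
  branch <- match.arg(branch)
  if (k < 2) stopf("k must be >= 2")
  class_sizes <- table(dataset$labels)
  if (any(class_sizes < k))
    stopf("class '%s' has fewer samples (%d) than k = %d; choose a smaller k",
          names(class_sizes)[which.min(class_sizes)], min(class_sizes), k)
  strata <- if (all(is.na(dataset$concentrations))) dataset$labels
            else paste(dataset$labels, dataset$concentrations)
  folds <- stratified_folds(strata, k, seed)

  n <- n_samples(dataset)
  decision <- rep(NA_real_, n)
  positive <- rep(NA, n)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- which(!tr)
    if (length(te) == 0) next
    train_ds <- labelled_dataset(
      lapply(dataset$blocks, function(b)
        feature_block(b$name, b$matrix[tr, , drop = FALSE],
                      variable_axis = b$variable_axis, provenance = b$provenance)),
      dataset$labels[tr], dataset$concentrations[tr])
    pipe <- train_pipeline(train_ds, level = level, analyte = analyte, ...)
    res <- predict_pipeline(pipe, dataset, rows = te)
    if (level == "hldf" && branch == "ims") {
      decision[te] <- res$f; positive[te] <- res$ims_positive
    } else if (level == "hldf" && branch == "gc") {
      decision[te] <- res$dM; positive[te] <- res$gc_positive
    } else {
      decision[te] <- res$f %||% res$dM; positive[te] <- res$positive
    }
  }
  is_target <- dataset$labels == analyte
  counts <- confusion_counts(tp = sum(is_target & positive),
                             fn = sum(is_target & !positive),
                             fp = sum(!is_target & positive),
                             tn = sum(!is_target & !positive))
  metrics <- suppressMessages(classification_metrics(counts))
  structure(list(level = level, analyte = analyte, branch = branch,
                 k = k, seed = seed, folds = folds, counts = counts,
                 precision = metrics$precision, recall = metrics$recall,
                 f1 = metrics$f1, accuracy = metrics$accuracy,
                 decisions = data.frame(row = seq_len(n),
                                        label = dataset$labels,
                                        concentration = dataset$concentrations,
                                        fold = folds, decision = decision,
                                        positive = positive)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s '%s'%s  k=%d seed=%d\n",
              toupper(x$level), x$analyte,
              if (x$level == "hldf") paste0(" [", x$branch, "]") else "",
              x$k, x$seed))
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d  P=%.3f R=%.3f F1=%.3f acc=%.3f\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn,
              x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Spread of decision values across concentration groups
#'
#' Max minus min of the per-concentration mean held-out decision values; the
#' mid-level strategy's feature extraction is expected to shrink this spread
#' relative to low-level fusion (concentration robustness).
#'
#' @param report A [kfold_evaluate()] result on a corpus with concentrations.
#' @return Nonnegative scalar.
#' @export
concentration_spread <- function(report) {
  d <- report$decisions
  d <- d[!is.na(d$concentration) & !is.na(d$decision), ]
  if (nrow(d) == 0) stopf("report carries no concentration-tagged decisions")
  m <- tapply(d$decision, d$concentration, mean)
  max(m) - min(m)
}

#' Wall-clock timing of pipeline fit and prediction
#'
#' Informational only (hardware-dependent): seconds to train on a split of
#' the corpus and to batch-classify the held-out rows.
#'
#' @param dataset A [labelled_dataset()].
#' @param level,analyte,... Passed to [train_pipeline()].
#' @param train_fraction Fraction of rows used for fitting. Default 0.8.
#' @param seed Seed for the split.
#' @return List with `fit_seconds`, `predict_seconds`, `n_train`, `n_test`;
#'   serialize with [jsonlite::toJSON()].
#' @export
timing_report <- function(dataset, level, analyte, train_fraction = 0.8,
                          seed = 1, ...) {
  n <- n_samples(dataset)
  tr <- with_seed(seed, sample(n, ceiling(train_fraction * n)))
  train_ds <- labelled_dataset(
    lapply(dataset$blocks, function(b)
      feature_block(b$name, b$matrix[tr, , drop = FALSE],
                    variable_axis = b$variable_axis, provenance = b$provenance)),
    dataset$labels[tr], dataset$concentrations[tr])
  t_fit <- system.time(
    pipe <- train_pipeline(train_ds, level = level, analyte = analyte, ...))
  te <- setdiff(seq_len(n), tr)
  t_pred <- system.time(predict_pipeline(pipe, dataset, rows = te))
  list(fit_seconds = unname(t_fit["elapsed"]),
       predict_seconds = unname(t_pred["elapsed"]),
       n_train = length(tr), n_test = length(te))
}
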