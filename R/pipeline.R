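# End-to-end trained fusion pipelines and the gated fuse() entry point.

default_threshold <- function(level, analyte) {
  # Published decision-function thresholds: LLDF 0.0; MLDF -0.02 (DMMP) and
  # -0.10 (acetone); the HLDF IMS branch uses 0.0 (the value tied to the
  # reported result; the alternative -0.5 boundary is available via the
  # threshold argument).
  if (level == "mldf") {
    switch(tolower(analyte), dmmp = -0.02, acetone = -0.10, -0.02)
  } else 0.0
}

#' Train a fusion pipeline for one target analyte
#'
#' Fits every stage on the supplied data only (use inside cross-validation
#' folds to keep train/test hygiene): autoscaling on the target-class IMS
#' rows, SNV on the spectra, then the level-specific model --
#' `lldf`: one-class SVM on the concatenated blocks;
#' `mldf`: per-block PCA at the explained-variance criterion, scores + RT,
#' one-class SVM;
#' `hldf`: one-class SVM on the raw plasmagram trace (the stable reactant-ion
#' peak anchors the linear boundary; see the methods vignette) plus a SIMCA
#' class model on [SNV spectra | RT].
#'
#' @param dataset A [labelled_dataset()] with blocks `ims`, `qepas`, `rt`.
#' @param level `"lldf"`, `"mldf"` or `"hldf"`.
#' @param analyte Target analyte label; one-class training uses only its rows.
#' @param kernel,nu One-class SVM settings (see [ocsvm_fit()]).
#' @param threshold Decision threshold tau; `NULL` selects the published
#'   default for the level/analyte.
#' @param ev Explained-variance criterion for MLDF PCA and SIMCA. Default 0.99.
#' @param dE_max,dM_max SIMCA distance limits. Defaults 5.5 and 6.5.
#' @param rule HLDF combination rule. Default `"any"`.
#' @return An object of class `fusion_pipeline`.
#' @export
train_pipeline <- function(dataset, level = c("lldf", "mldf", "hldf"), analyte,
                           kernel = "linear", nu = 0.02, threshold = NULL,
                           ev = 0.99, dE_max = 5.5, dM_max = 6.5,
                           rule = c("any", "all")) {
  level <- match.arg(level)
  rule <- match.arg(rule)
  for (b in c("ims", "qepas", "rt"))
    if (is.null(dataset$blocks[[b]])) stopf("dataset lacks required block '%s'", b)
  rows <- dataset$labels == analyte
  if (sum(rows) < 3) stopf("need at least 3 samples of analyte '%s'", analyte)
  threshold <- threshold %||% default_threshold(level, analyte)

  sub_block <- function(name) {
    b <- dataset$blocks[[name]]
    feature_block(b$name, b$matrix[rows, , drop = FALSE],
                  variable_axis = b$variable_axis, provenance = b$provenance)
  }
  ims_raw <- sub_block("ims")
  qepas_raw <- sub_block("qepas")
  rt <- as.numeric(dataset$blocks$rt$matrix[rows, 1])

  pipe <- list(level = level, analyte = analyte, threshold = threshold,
               kernel = kernel, nu = nu, ev = ev, rule = rule,
               drift_grid = ims_raw$variable_axis,
               wavelength_grid = qepas_raw$variable_axis)

  qepas_snv <- snv_block(qepas_raw)
  if (level %in% c("lldf", "mldf")) {
    scaler <- autoscale_fit(ims_raw)
    ims_sc <- autoscale_apply(ims_raw, scaler)
    pipe$autoscale <- scaler
    if (level == "lldf") {
      feats <- lldf_assemble(ims_sc, qepas_snv, rt)
    } else {
      pipe$pca <- pca_blocks_fit(list(ims = ims_sc, qepas = qepas_snv), ev = ev)
      feats <- mldf_assemble(ims_sc, qepas_snv, rt, pipe$pca)
    }
    pipe$ocsvm <- ocsvm_fit(feats, kernel = kernel, nu = nu, threshold = threshold)
  } else {
    pipe$ocsvm <- ocsvm_fit(ims_raw, kernel = kernel, nu = nu, threshold = threshold)
    pipe$simca <- simca_fit(cbind(qepas_snv$matrix, rt = rt), label = analyte,
                            ev = ev, dE_max = dE_max, dM_max = dM_max)
  }
  structure(pipe, class = "fusion_pipeline")
}

#' @export
print.fusion_pipeline <- function(x, ...) {
  cat(sprintf("<fusion_pipeline> %s for '%s' (kernel=%s, nu=%g, tau=%g)\n",
              toupper(x$level), x$analyte, x$kernel, x$nu, x$threshold))
  invisible(x)
}

# Classify raw per-sample blocks (matrices aligned by row) with a trained
# pipeline. Returns a data frame; columns depend on the level.
pipeline_classify <- function(pipe, ims_matrix, qepas_matrix, rt) {
  ims_b <- feature_block("ims", ims_matrix, variable_axis = pipe$drift_grid)
  qepas_b <- feature_block("qepas", qepas_matrix, variable_axis = pipe$wavelength_grid)
  qepas_snv <- snv_block(qepas_b)
  if (pipe$level == "lldf") {
    feats <- lldf_assemble(autoscale_apply(ims_b, pipe$autoscale), qepas_snv, rt)
    res <- ocsvm_classify(pipe$ocsvm, feats)
    data.frame(f = res$f, positive = res$inlier)
  } else if (pipe$level == "mldf") {
    feats <- mldf_assemble(autoscale_apply(ims_b, pipe$autoscale), qepas_snv,
                           rt, pipe$pca)
    res <- ocsvm_classify(pipe$ocsvm, feats)
    data.frame(f = res$f, positive = res$inlier)
  } else {
    ims_res <- ocsvm_classify(pipe$ocsvm, ims_matrix)
    gc_res <- simca_classify(pipe$simca, cbind(qepas_snv$matrix, rt = rt))
    combined <- vapply(seq_len(nrow(ims_res)), function(i) {
      hldf_combine(ims_res[i, , drop = FALSE], gc_res[i, , drop = FALSE],
                   rule = pipe$rule)$positive
    }, TRUE)
    data.frame(f = ims_res$f, ims_positive = ims_res$inlier,
               dE = gc_res$dE, dM = gc_res$dM, gc_positive = gc_res$positive,
               positive = combined)
  }
}

#' Classify dataset rows with a trained pipeline
#'
#' @param pipeline A [train_pipeline()] result.
#' @param dataset A [labelled_dataset()] with blocks `ims`, `qepas`, `rt`.
#' @param rows Optional logical or integer row selector.
#' @return Data frame of per-row decisions; for `lldf`/`mldf` columns `f` and
#'   `positive`, for `hldf` additionally the per-sensor evidence.
#' @export
predict_pipeline <- function(pipeline, dataset, rows = NULL) {
  if (!inherits(pipeline, "fusion_pipeline")) stopf("pipeline must be a fusion_pipeline")
  rows <- rows %||% seq_along(dataset$labels)
  pipeline_classify(pipeline,
                    dataset$blocks$ims$matrix[rows, , drop = FALSE],
                    dataset$blocks$qepas$matrix[rows, , drop = FALSE],
                    as.numeric(dataset$blocks$rt$matrix[rows, 1]))
}

#' Fuse a co-located IMS / GC-QEPAS reading pair
#'
#' Runs the configured fusion level end-to-end on one reading pair, but only
#' after the co-location gate passes; a failed gate raises a condition of
#' class `chemfuse_gate_error` carrying the [require_fusable()] decision, and
#' no classification is performed.
#'
#' @param ims_reading An IMS [sensor_reading()].
#' @param gc_reading A GC-QEPAS [sensor_reading()].
#' @param pipeline A [train_pipeline()] result.
#' @param cutoff,mode,time_window Gate settings (see [require_fusable()]).
#' @return An object of class `fusion_verdict`: fields `analyte`, `level`,
#'   `positive`, `evidence` (decision values / distances and per-sensor
#'   verdicts) and `gate`.
#' @export
fuse <- function(ims_reading, gc_reading, pipeline, cutoff = 1.0,
                 mode = c("per_axis", "euclidean"), time_window = 300) {
  mode <- match.arg(mode)
  if (ims_reading$sensor != "IMS" || gc_reading$sensor != "GCQEPAS")
    stopf("fuse expects an IMS reading and a GCQEPAS reading, in that order")
  gate <- require_fusable(ims_reading, gc_reading, cutoff = cutoff, mode = mode,
                          time_window = time_window)
  if (!gate$fused) {
    cond <- structure(
      class = c("chemfuse_gate_error", "error", "condition"),
      list(message = sprintf(
        paste("co-location gate refused fusion (d = %.3f m, cutoff = %g m,",
              "mode = %s); sensors operate independently"),
        gate$result$d, gate$cutoff, gate$mode),
        call = sys.call(), decision = gate))
    stop(cond)
  }
  ims_vec <- resample_signal(ims_reading$payload$current,
                             ims_reading$payload$drift_time, pipeline$drift_grid)
  sp <- gc_reading$payload$spectrum
  sp_vec <- resample_signal(sp$signal, sp$wavelength, pipeline$wavelength_grid)
  rt <- extract_rt(gc_reading$payload$chromatogram)
  res <- pipeline_classify(pipeline, matrix(ims_vec, nrow = 1),
                           matrix(sp_vec, nrow = 1), rt)
  structure(list(analyte = pipeline$analyte, level = toupper(pipeline$level),
                 positive = isTRUE(res$positive[1]),
                 evidence = c(as.list(res[1, , drop = FALSE]), rt = rt),
                 gate = gate),
            class = "fusion_verdict")
}

#' @export
print.fusion_verdict <- function(x, ...) {
  cat(sprintf("<fusion_verdict> %s %s: %s\n", x$level, x$analyte,
              if (x$positive) "POSITIVE" else "negative"))
  ev <- x$evidence
  cat("  evidence:", paste(sprintf("%s=%.4g", names(ev), unlist(ev)), collapse = " "), "\n")
  invisible(x)
}
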