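#' Feature block: a samples-by-variables matrix with provenance
#'
#' The unit that the fusion strategies concatenate. `provenance` is an ordered
#' character vector of preprocessing step descriptors (e.g. `"snv()"`,
#' `"autoscale(dropped=3)"`) recorded by every preprocessing operator; the
#' low-level fusion assembler refuses blocks that lack the required steps.
#'
#' @param name Block name.
#' @param matrix Numeric matrix, n_samples x n_variables.
#' @param variable_axis Optional [axis_grid()]; its length must equal the
#'   number of columns.
#' @param provenance Character vector of applied preprocessing descriptors.
#' @return An object of class `feature_block`.
#' @export
feature_block <- function(name, matrix, variable_axis = NULL,
                          provenance = character()) {
  if (!is.character(name) || length(name) != 1) stopf("block name must be a string")
  if (!is.matrix(matrix) || !is.numeric(matrix)) stopf("block matrix must be numeric")
  if (any(!is.finite(matrix))) stopf("block matrix must be finite")
  if (!is.null(variable_axis)) {
    if (!inherits(variable_axis, "axis_grid")) stopf("variable_axis must be an axis_grid")
    if (length(variable_axis$values) != ncol(matrix))
      stopf("variable_axis length (%d) must equal ncol(matrix) (%d)",
            length(variable_axis$values), ncol(matrix))
  }
  structure(list(name = name, matrix = matrix, variable_axis = variable_axis,
                 provenance = as.character(provenance)),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> '%s' %d x %d  [%s]\n", x$name,
              nrow(x$matrix), ncol(x$matrix),
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

#' Labelled multi-block dataset
#'
#' Named feature blocks sharing one sample dimension, aligned with labels and
#' concentrations by row.
#'
#' @param blocks Named list of [feature_block()]s with identical row counts.
#' @param labels Character vector, one label per sample.
#' @param concentrations Optional numeric vector (ppb), one per sample.
#' @return An object of class `labelled_dataset`.
#' @export
labelled_dataset <- function(blocks, labels, concentrations = NULL) {
  if (!is.list(blocks) || length(blocks) == 0 || is.null(names(blocks)) ||
      any(names(blocks) == ""))
    stopf("blocks must be a non-empty named list")
  if (!all(vapply(blocks, inherits, TRUE, "feature_block")))
    stopf("all blocks must be feature_block objects")
  n <- nrow(blocks[[1]]$matrix)
  if (!all(vapply(blocks, function(b) nrow(b$matrix), 1L) == n))
    stopf("all blocks must share the same number of samples")
  labels <- as.character(labels)
  if (length(labels) != n) stopf("labels length (%d) must equal n_samples (%d)",
                                 length(labels), n)
  if (is.null(concentrations)) concentrations <- rep(NA_real_, n)
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != n) stopf("concentrations length must equal n_samples")
  structure(list(blocks = blocks, labels = labels, concentrations = concentrations),
            class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf("<labelled_dataset> %d samples, blocks: %s\n",
              length(x$labels),
              paste(sprintf("%s[%d]", names(x$blocks),
                            vapply(x$blocks, function(b) ncol(b$matrix), 1L)),
                    collapse = ", ")))
  print(table(x$labels))
  invisible(x)
}

n_samples <- function(dataset) length(dataset$labels)

#' Assemble a labelled dataset from samples
#'
#' Stacks per-sample payload channels into feature blocks, one row per sample
#' in input order. All samples must carry the channels named in `block_spec`
#' and share payload axes; resample first (see [resample_signal()]) if they do
#' not.
#'
#' @param samples List of [sample_record()]s.
#' @param block_spec Named character vector mapping block names to payload
#'   channels: `"plasmagram"` (IMS current trace), `"spectrum"` (IR signal),
#'   `"chromatogram"` (GC trace), or `"rt"` (scalar retention time extracted
#'   with [extract_rt()]).
#' @return A [labelled_dataset()].
#' @examples
#' \dontrun{
#' ds <- assemble_dataset(samples, c(ims = "plasmagram", qepas = "spectrum", rt = "rt"))
#' }
#' @export
assemble_dataset <- function(samples,
                             block_spec = c(ims = "plasmagram", qepas = "spectrum",
                                            rt = "rt")) {
  if (length(samples) == 0) stopf("samples must be non-empty")
  if (!all(vapply(samples, inherits, TRUE, "sample_record")))
    stopf("samples must be sample_record objects")
  allowed <- c("plasmagram", "spectrum", "chromatogram", "rt")
  if (is.null(names(block_spec)) || !all(block_spec %in% allowed))
    stopf("block_spec must be a named vector with channels among: %s",
          paste(allowed, collapse = ", "))

  channel_of <- function(sample, channel) {
    if (channel == "plasmagram") {
      r <- find_reading(sample, "IMS")
      if (is.null(r)) stopf("a sample lacks the IMS channel required by block_spec")
      list(values = r$payload$current, axis = r$payload$drift_time)
    } else {
      r <- find_reading(sample, "GCQEPAS")
      if (is.null(r)) stopf("a sample lacks the GCQEPAS channel required by block_spec")
      switch(channel,
        spectrum = list(values = r$payload$spectrum$signal,
                        axis = r$payload$spectrum$wavelength),
        chromatogram = list(values = r$payload$chromatogram$signal,
                            axis = r$payload$chromatogram$time),
        rt = list(values = extract_rt(r$payload$chromatogram), axis = NULL))
    }
  }

  blocks <- list()
  for (bn in names(block_spec)) {
    ch <- block_spec[[bn]]
    rows <- lapply(samples, channel_of, channel = ch)
    axis <- rows[[1]]$axis
    if (!is.null(axis)) {
      for (r in rows[-1]) {
        if (!axes_equal(axis, r$axis))
          stopf("samples differ on the '%s' axis; resample them onto a common grid first", ch)
      }
    }
    m <- do.call(rbind, lapply(rows, function(r) r$values))
    blocks[[bn]] <- feature_block(bn, m, variable_axis = axis)
  }
  labels <- vapply(samples, function(s) s$label %||% NA_character_, "")
  conc <- vapply(samples, function(s) s$concentration %||% NA_real_, 0)
  labelled_dataset(blocks, labels, conc)
}
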