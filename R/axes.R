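#' Axis grid for a sensor trace
#'
#' A validated, strictly increasing sampling axis with a fixed unit. Units are
#' fixed at the package boundary: `"ms"` for IMS drift time, `"s"` for
#' chromatogram time, `"um"` for IR wavelength. No unit inference is performed.
#'
#' @param values Numeric vector, strictly increasing, length >= 2.
#' @param unit One of `"ms"`, `"s"`, `"um"`.
#' @return An object of class `axis_grid` with fields `values` and `unit`.
#' @examples
#' axis_grid(seq(4, 16, by = 0.1), "ms")
#' @export
axis_grid <- function(values, unit = c("ms", "s", "um")) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 2) stopf("axis grid needs at least 2 points")
  if (any(!is.finite(values))) stopf("axis grid values must be finite")
  if (any(diff(values) <= 0)) stopf("axis grid must be strictly increasing")
  structure(list(values = values, unit = unit), class = "axis_grid")
}

as_axis_grid <- function(x, unit) {
  if (inherits(x, "axis_grid")) {
    if (x$unit != unit) stopf("axis unit '%s' does not match expected '%s'", x$unit, unit)
    return(x)
  }
  axis_grid(x, unit)
}

#' @export
print.axis_grid <- function(x, ...) {
  cat(sprintf("<axis_grid> %d points, %g..%g %s\n",
              length(x$values), min(x$values), max(x$values), x$unit))
  invisible(x)
}

#' @export
length.axis_grid <- function(x) length(x$values)

axes_equal <- function(a, b, tol = 1e-9) {
  a$unit == b$unit && length(a$values) == length(b$values) &&
    all(abs(a$values - b$values) <= tol * pmax(1, abs(a$values)))
}
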