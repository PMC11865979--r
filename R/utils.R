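# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  force(code)
}

# Deterministic sub-seed derivation; stays inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + as.numeric(i) * 8191) %% 2147483647)
}

# Unnormalized Gaussian profile used by the trace generators and fixtures.
gaussian_profile <- function(x, center, width) {
  exp(-((x - center)^2) / (2 * width^2))
}

# Centered moving average; edge positions fall back to the raw values.
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) window <- window + 1L
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite_matrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m)) stopf("%s must be a numeric matrix", what)
  if (any(!is.finite(m))) stopf("%s contains non-finite values", what)
  invisible(m)
}
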