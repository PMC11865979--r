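# The spatial co-location gate: sensors may only be fused when their readings
# were taken close enough together that they sampled the same substance.

#' Distance between two sensor positions with error propagation
#'
#' Per-axis absolute separations, the Euclidean distance, and first-order
#' propagated uncertainties: per axis `sigma_axis = sqrt(s1^2 + s2^2)`, and
#' for the Euclidean distance
#' `sigma_d = sqrt(sum((delta_axis / d)^2 * sigma_axis^2))` (the maximum axis
#' sigma when `d = 0`).
#'
#' @param p1,p2 [sensor_position()]s.
#' @return An object of class `distance_result` with fields `dx`, `dy`, `dz`,
#'   `d`, `sigma_x`, `sigma_y`, `sigma_z`, `sigma_d`.
#' @examples
#' a <- sensor_position(0, 0, 0); b <- sensor_position(0.5, 0.5, 0.5)
#' sensor_distance(a, b)$d  # sqrt(0.75)
#' @export
sensor_distance <- function(p1, p2) {
  if (!inherits(p1, "sensor_position") || !inherits(p2, "sensor_position"))
    stopf("p1 and p2 must be sensor_position objects")
  dd <- abs(c(p1$x - p2$x, p1$y - p2$y, p1$z - p2$z))
  d <- sqrt(sum(dd^2))
  sig <- sqrt(c(p1$sigma_x^2 + p2$sigma_x^2,
                p1$sigma_y^2 + p2$sigma_y^2,
                p1$sigma_z^2 + p2$sigma_z^2))
  sigma_d <- if (d == 0) max(sig) else sqrt(sum((dd / d)^2 * sig^2))
  structure(list(dx = dd[1], dy = dd[2], dz = dd[3], d = d,
                 sigma_x = sig[1], sigma_y = sig[2], sigma_z = sig[3],
                 sigma_d = sigma_d),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance> dx=%.4f dy=%.4f dz=%.4f  d=%.4f +/- %.4f m\n",
              x$dx, x$dy, x$dz, x$d, x$sigma_d))
  invisible(x)
}

#' The co-location gate decision
#'
#' Default (`per_axis`) mode: fuse only when every axis separation plus its
#' propagated uncertainty is below the cutoff (1 m indoors). Uncertainty
#' counts against fusion -- fusing readings of different substances is the
#' failure mode the gate exists to prevent. `euclidean` mode compares
#' `d + sigma_d` against the cutoff instead.
#'
#' @param p1,p2 [sensor_position()]s.
#' @param cutoff Gate cutoff in m, > 0. Default 1.
#' @param mode `"per_axis"` (default) or `"euclidean"`.
#' @return An object of class `gate_decision` with fields `fused`, `result`
#'   (the [sensor_distance()]), `cutoff`, `mode`.
#' @examples
#' colocation_gate(sensor_position(0, 0, 0), sensor_position(0.3, 0.3, 0.3))$fused
#' @export
colocation_gate <- function(p1, p2, cutoff = 1.0,
                            mode = c("per_axis", "euclidean")) {
  mode <- match.arg(mode)
  if (!is.finite(cutoff) || cutoff <= 0) stopf("cutoff must be > 0")
  res <- sensor_distance(p1, p2)
  fused <- if (mode == "per_axis") {
    (res$dx + res$sigma_x < cutoff) &&
      (res$dy + res$sigma_y < cutoff) &&
      (res$dz + res$sigma_z < cutoff)
  } else {
    res$d + res$sigma_d < cutoff
  }
  structure(list(fused = fused, result = res, cutoff = cutoff, mode = mode),
            class = "gate_decision")
}

#' @export
print.gate_decision <- function(x, ...) {
  cat(sprintf("<gate> %s (mode=%s, cutoff=%g m, d=%.4f m)\n",
              if (x$fused) "FUSED" else "NOT FUSED", x$mode, x$cutoff, x$result$d))
  invisible(x)
}

#' Gate two sensor readings for fusion
#'
#' Combines the spatial gate with a temporal co-location window (the analyte
#' cloud disperses over time; default 300 s, configurable). Downstream fusion
#' refuses to run when the returned decision has `fused = FALSE`.
#'
#' @param r1,r2 [sensor_reading()]s from two distinct sensor types.
#' @param cutoff,mode Passed to [colocation_gate()].
#' @param time_window Maximum timestamp difference in s.
#' @return A `gate_decision` with extra fields `spatial`, `temporal` and
#'   `dt_seconds`; `fused` is their conjunction.
#' @export
require_fusable <- function(r1, r2, cutoff = 1.0,
                            mode = c("per_axis", "euclidean"),
                            time_window = 300) {
  mode <- match.arg(mode)
  if (!inherits(r1, "sensor_reading") || !inherits(r2, "sensor_reading"))
    stopf("r1 and r2 must be sensor_reading objects")
  if (r1$sensor == r2$sensor)
    stopf("fusion requires readings from two distinct sensors, got two '%s'", r1$sensor)
  g <- colocation_gate(r1$position, r2$position, cutoff = cutoff, mode = mode)
  dt <- abs(r1$timestamp - r2$timestamp)
  temporal <- dt <= time_window
  g$spatial <- g$fused
  g$temporal <- temporal
  g$dt_seconds <- dt
  g$fused <- g$fused && temporal
  g
}
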