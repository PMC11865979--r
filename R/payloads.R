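#' IMS plasmagram
#'
#' The raw output trace of an ion mobility spectrometer: ion current (nA)
#' versus drift time (ms). Instrument pressure and temperature are carried as
#' context for mobility work; the drift tube here runs subatmospheric
#' (600 mbar default) in negative polarity.
#'
#' @param drift_time An [axis_grid()] in ms (or a numeric vector, coerced).
#' @param current Numeric vector of ion currents (nA), same length as the axis.
#' @param polarity `"negative"` (default) or `"positive"`.
#' @param pressure Drift-tube pressure in mbar, > 0.
#' @param temperature Drift-tube temperature in K, > 0.
#' @return An object of class `plasmagram`.
#' @examples
#' dt <- seq(4, 16, by = 0.1)
#' p <- plasmagram(dt, exp(-(dt - 8)^2) * 5)
#' @export
plasmagram <- function(drift_time, current, polarity = c("negative", "positive"),
                       pressure = 600, temperature = 298.15) {
  polarity <- match.arg(polarity)
  drift_time <- as_axis_grid(drift_time, "ms")
  current <- as.numeric(current)
  if (length(current) != length(drift_time$values))
    stopf("current length (%d) must match drift_time length (%d)",
          length(current), length(drift_time$values))
  if (any(!is.finite(current))) stopf("current must be finite")
  if (!is.finite(pressure) || pressure <= 0) stopf("pressure must be > 0")
  if (!is.finite(temperature) || temperature <= 0) stopf("temperature must be > 0")
  structure(list(drift_time = drift_time, current = current, polarity = polarity,
                 pressure = pressure, temperature = temperature),
            class = "plasmagram")
}

#' GC chromatogram
#'
#' Detector signal versus retention time for the GC channel of the GC-QEPAS
#' sensor; the retention time of the dominant peak is the scalar feature used
#' downstream.
#'
#' @param time An [axis_grid()] in s (or numeric vector, coerced); values >= 0.
#' @param signal Numeric vector, same length as `time`.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(time, signal) {
  time <- as_axis_grid(time, "s")
  if (any(time$values < 0)) stopf("chromatogram time values must be >= 0")
  signal <- as.numeric(signal)
  if (length(signal) != length(time$values))
    stopf("signal length (%d) must match time length (%d)",
          length(signal), length(time$values))
  if (any(!is.finite(signal))) stopf("signal must be finite")
  structure(list(time = time, signal = signal), class = "chromatogram")
}

#' Photoacoustic IR spectrum
#'
#' QEPAS signal versus wavelength over the quantum-cascade-laser sweep range,
#' 7.4 to 10.7 um by default.
#'
#' @param wavelength An [axis_grid()] in um (or numeric vector, coerced).
#' @param signal Numeric vector, same length as `wavelength`.
#' @param range Allowed wavelength range, default `c(7.4, 10.7)`.
#' @return An object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavelength, signal, range = c(7.4, 10.7)) {
  wavelength <- as_axis_grid(wavelength, "um")
  tol <- 1e-9
  if (min(wavelength$values) < range[1] - tol || max(wavelength$values) > range[2] + tol)
    stopf("wavelengths must lie within [%g, %g] um", range[1], range[2])
  signal <- as.numeric(signal)
  if (length(signal) != length(wavelength$values))
    stopf("signal length (%d) must match wavelength length (%d)",
          length(signal), length(wavelength$values))
  if (any(!is.finite(signal))) stopf("signal must be finite")
  structure(list(wavelength = wavelength, signal = signal, range = range),
            class = "ir_spectrum")
}

#' Sensor position with measurement-error budget
#'
#' Cartesian position (m) of a sensor's sampler relative to the scene
#' reference point "000", together with per-axis measurement standard errors.
#' Defaults attach by measuring device: 0.01 m for a measuring tape (its
#' minimum measurable distance), 0.0015 m for a laser distance meter (user
#' manual figure). Explicit sigmas override the device default per axis.
#'
#' @param x,y,z Coordinates in m.
#' @param device `"tape"` or `"laser"`; sets default sigmas.
#' @param sigma_x,sigma_y,sigma_z Optional per-axis standard errors (m), > 0.
#' @return An object of class `sensor_position`.
#' @examples
#' sensor_position(0.5, 1.2, 0, device = "laser")
#' @export
sensor_position <- function(x, y, z, device = c("tape", "laser"),
                            sigma_x = NULL, sigma_y = NULL, sigma_z = NULL) {
  device <- match.arg(device)
  default_sigma <- switch(device, tape = 0.01, laser = 0.0015)
  s <- c(sigma_x %||% default_sigma, sigma_y %||% default_sigma, sigma_z %||% default_sigma)
  xyz <- c(x, y, z)
  if (length(xyz) != 3 || any(!is.finite(xyz))) stopf("x, y, z must be finite scalars")
  if (any(!is.finite(s)) || any(s <= 0)) stopf("position sigmas must be > 0")
  structure(list(x = x, y = y, z = z,
                 sigma_x = s[1], sigma_y = s[2], sigma_z = s[3],
                 device = device),
            class = "sensor_position")
}

#' A single tagged sensor reading
#'
#' Binds a payload to the sensor type that produced it, its position in the
#' scene and an acquisition timestamp. The payload kind must match the sensor:
#' a [plasmagram()] for `"IMS"`, a list with elements `chromatogram` and
#' `spectrum` for `"GCQEPAS"`.
#'
#' @param sensor `"IMS"` or `"GCQEPAS"`.
#' @param position A [sensor_position()].
#' @param payload Payload matching the sensor kind (see Details).
#' @param timestamp Acquisition time in seconds (numeric; any epoch).
#' @return An object of class `sensor_reading`.
#' @export
sensor_reading <- function(sensor = c("IMS", "GCQEPAS"), position, payload,
                           timestamp = 0) {
  sensor <- match.arg(sensor)
  if (!inherits(position, "sensor_position")) stopf("position must be a sensor_position")
  if (!is.numeric(timestamp) || length(timestamp) != 1 || !is.finite(timestamp))
    stopf("timestamp must be a finite numeric scalar")
  if (sensor == "IMS") {
    if (!inherits(payload, "plasmagram"))
      stopf("IMS reading requires a plasmagram payload")
  } else {
    ok <- is.list(payload) && inherits(payload$chromatogram, "chromatogram") &&
      inherits(payload$spectrum, "ir_spectrum")
    if (!ok) stopf("GCQEPAS reading requires a list(chromatogram=, spectrum=) payload")
    payload <- payload[c("chromatogram", "spectrum")]
  }
  structure(list(sensor = sensor, timestamp = timestamp,
                 position = position, payload = payload),
            class = "sensor_reading")
}

#' A labelled sample of co-acquired readings
#'
#' @param label Optional analyte name.
#' @param concentration Optional concentration in ppb, > 0 when present.
#' @param readings List of [sensor_reading()] objects.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(label = NULL, concentration = NULL, readings = list()) {
  if (!is.null(concentration)) {
    if (!is.numeric(concentration) || length(concentration) != 1 ||
        !is.finite(concentration) || concentration <= 0)
      stopf("concentration, if present, must be > 0")
  }
  if (!is.list(readings) || !all(vapply(readings, inherits, TRUE, "sensor_reading")))
    stopf("readings must be a list of sensor_reading objects")
  structure(list(label = label, concentration = concentration, readings = readings),
            class = "sample_record")
}

find_reading <- function(sample, sensor) {
  for (r in sample$readings) if (r$sensor == sensor) return(r)
  NULL
}
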