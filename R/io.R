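# File I/O for sensor readings and scene directories.
#
# Dialect: the numeric trace lives in a two-column CSV with a header row
# (drift_time_ms,current_nA / time_s,signal / wavelength_um,signal); typed
# metadata (sensor, position, device, polarity, pressure, temperature) lives
# in a JSON sidecar. fmt = "json" embeds traces and metadata in one document.
# Scene layout: <dir>/<sample-id>/<sensor>.csv (+ .json sidecars) with a
# sample.json holding label and concentration.

position_to_list <- function(p) {
  list(x = p$x, y = p$y, z = p$z, sigma_x = p$sigma_x, sigma_y = p$sigma_y,
       sigma_z = p$sigma_z, device = p$device)
}

position_from_list <- function(l) {
  for (f in c("x", "y", "z", "device"))
    if (is.null(l[[f]])) stopf("parse error: position is missing field '%s'", f)
  sensor_position(l$x, l$y, l$z, device = l$device,
                  sigma_x = l$sigma_x, sigma_y = l$sigma_y, sigma_z = l$sigma_z)
}

reading_to_list <- function(reading) {
  base <- list(sensor = reading$sensor, timestamp = reading$timestamp,
               position = position_to_list(reading$position))
  if (reading$sensor == "IMS") {
    p <- reading$payload
    base$plasmagram <- list(drift_time_ms = p$drift_time$values, current_nA = p$current,
                            polarity = p$polarity, pressure = p$pressure,
                            temperature = p$temperature)
  } else {
    base$chromatogram <- list(time_s = reading$payload$chromatogram$time$values,
                              signal = reading$payload$chromatogram$signal)
    base$spectrum <- list(wavelength_um = reading$payload$spectrum$wavelength$values,
                          signal = reading$payload$spectrum$signal)
  }
  base
}

reading_from_list <- function(l) {
  for (f in c("sensor", "position"))
    if (is.null(l[[f]])) stopf("parse error: reading is missing field '%s'", f)
  pos <- position_from_list(l$position)
  ts <- l$timestamp %||% 0
  if (identical(l$sensor, "IMS")) {
    pl <- l$plasmagram
    if (is.null(pl)) stopf("parse error: IMS reading is missing field 'plasmagram'")
    payload <- plasmagram(unlist(pl$drift_time_ms), unlist(pl$current_nA),
                          polarity = pl$polarity %||% "negative",
                          pressure = pl$pressure %||% 600,
                          temperature = pl$temperature %||% 298.15)
    sensor_reading("IMS", pos, payload, ts)
  } else if (identical(l$sensor, "GCQEPAS")) {
    if (is.null(l$chromatogram)) stopf("parse error: GCQEPAS reading is missing field 'chromatogram'")
    if (is.null(l$spectrum)) stopf("parse error: GCQEPAS reading is missing field 'spectrum'")
    payload <- list(
      chromatogram = chromatogram(unlist(l$chromatogram$time_s), unlist(l$chromatogram$signal)),
      spectrum = ir_spectrum(unlist(l$spectrum$wavelength_um), unlist(l$spectrum$signal)))
    sensor_reading("GCQEPAS", pos, payload, ts)
  } else {
    stopf("parse error: unknown sensor '%s'", l$sensor)
  }
}

strip_ext <- function(path) sub("\\.(json|csv)$", "", path)

write_trace_csv <- function(path, col1, values1, col2, values2) {
  df <- data.frame(values1, values2)
  names(df) <- c(col1, col2)
  utils::write.csv(df, path, row.names = FALSE)
}

read_trace_csv <- function(path, col1, col2) {
  if (!file.exists(path)) stopf("trace file not found: %s", path)
  df <- utils::read.csv(path)
  if (!all(c(col1, col2) %in% names(df)))
    stopf("parse error: %s must have columns '%s' and '%s'", path, col1, col2)
  df
}

#' Write a sensor reading to disk
#'
#' @param reading A [sensor_reading()].
#' @param path Destination path. For `fmt = "json"` the single output file;
#'   for `fmt = "csv"` a base path (an extension, if given, is stripped) from
#'   which the trace CSVs and the `.json` metadata sidecar are derived.
#' @param fmt `"json"` or `"csv"`.
#' @return The main path written, invisibly.
#' @seealso [read_reading()]
#' @export
write_reading <- function(reading, path, fmt = c("json", "csv")) {
  fmt <- match.arg(fmt)
  if (!inherits(reading, "sensor_reading")) stopf("reading must be a sensor_reading")
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("destination directory does not exist: %s", dir)
  if (fmt == "json") {
    jsonlite::write_json(reading_to_list(reading), path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  base <- strip_ext(path)
  meta <- list(sensor = reading$sensor, timestamp = reading$timestamp,
               position = position_to_list(reading$position))
  if (reading$sensor == "IMS") {
    p <- reading$payload
    write_trace_csv(paste0(base, ".csv"), "drift_time_ms", p$drift_time$values,
                    "current_nA", p$current)
    meta$polarity <- p$polarity
    meta$pressure <- p$pressure
    meta$temperature <- p$temperature
    meta$trace <- basename(paste0(base, ".csv"))
  } else {
    write_trace_csv(paste0(base, ".chrom.csv"), "time_s",
                    reading$payload$chromatogram$time$values, "signal",
                    reading$payload$chromatogram$signal)
    write_trace_csv(paste0(base, ".spec.csv"), "wavelength_um",
                    reading$payload$spectrum$wavelength$values, "signal",
                    reading$payload$spectrum$signal)
    meta$chromatogram <- basename(paste0(base, ".chrom.csv"))
    meta$spectrum <- basename(paste0(base, ".spec.csv"))
  }
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(base, ".json"))
}

#' Read a sensor reading from disk
#'
#' Validates on construction: a malformed file raises a parse error naming the
#' offending field; a non-monotone axis raises a validation error.
#'
#' @param path Path written by [write_reading()] (for `fmt = "csv"`, the base
#'   path or the `.json` sidecar).
#' @param fmt `"json"` or `"csv"`.
#' @return A validated [sensor_reading()].
#' @export
read_reading <- function(path, fmt = c("json", "csv")) {
  fmt <- match.arg(fmt)
  if (fmt == "json") {
    if (!file.exists(path)) stopf("file not found: %s", path)
    return(reading_from_list(jsonlite::read_json(path, simplifyVector = FALSE)))
  }
  base <- strip_ext(path)
  meta_path <- paste0(base, ".json")
  if (!file.exists(meta_path)) stopf("metadata sidecar not found: %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  for (f in c("sensor", "position"))
    if (is.null(meta[[f]])) stopf("parse error: sidecar is missing field '%s'", f)
  pos <- position_from_list(meta$position)
  ts <- meta$timestamp %||% 0
  if (identical(meta$sensor, "IMS")) {
    df <- read_trace_csv(paste0(base, ".csv"), "drift_time_ms", "current_nA")
    payload <- plasmagram(df$drift_time_ms, df$current_nA,
                          polarity = meta$polarity %||% "negative",
                          pressure = meta$pressure %||% 600,
                          temperature = meta$temperature %||% 298.15)
    sensor_reading("IMS", pos, payload, ts)
  } else if (identical(meta$sensor, "GCQEPAS")) {
    dfc <- read_trace_csv(paste0(base, ".chrom.csv"), "time_s", "signal")
    dfs <- read_trace_csv(paste0(base, ".spec.csv"), "wavelength_um", "signal")
    payload <- list(chromatogram = chromatogram(dfc$time_s, dfc$signal),
                    spectrum = ir_spectrum(dfs$wavelength_um, dfs$signal))
    sensor_reading("GCQEPAS", pos, payload, ts)
  } else {
    stopf("parse error: unknown sensor '%s'", meta$sensor)
  }
}

#' Write a scene of samples to a directory
#'
#' Layout: `<dir>/sample-001/ims.*`, `<dir>/sample-001/gcqepas.*` plus a
#' `sample.json` with label and concentration per sample.
#'
#' @param samples Non-empty list of [sample_record()]s.
#' @param dir Output directory (created if missing).
#' @param fmt Passed to [write_reading()].
#' @return `dir`, invisibly.
#' @export
write_scene <- function(samples, dir, fmt = c("csv", "json")) {
  fmt <- match.arg(fmt)
  if (length(samples) == 0) stopf("refusing to write an empty scene")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    sdir <- file.path(dir, sprintf("sample-%03d", i))
    dir.create(sdir, showWarnings = FALSE)
    jsonlite::write_json(list(label = s$label, concentration = s$concentration),
                         file.path(sdir, "sample.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    for (r in s$readings) {
      nm <- tolower(r$sensor)
      write_reading(r, file.path(sdir, if (fmt == "json") paste0(nm, ".reading.json") else nm),
                    fmt = fmt)
    }
  }
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir Scene directory.
#' @param fmt Format the scene was written in.
#' @return List of [sample_record()]s in sample-id order.
#' @export
read_scene <- function(dir, fmt = c("csv", "json")) {
  fmt <- match.arg(fmt)
  if (!dir.exists(dir)) stopf("scene directory not found: %s", dir)
  sdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(sdirs) == 0) stopf("scene directory holds no samples: %s", dir)
  lapply(sdirs, function(sdir) {
    meta <- jsonlite::read_json(file.path(sdir, "sample.json"), simplifyVector = TRUE)
    readings <- list()
    for (nm in c("ims", "gcqepas")) {
      p <- file.path(sdir, if (fmt == "json") paste0(nm, ".reading.json") else paste0(nm, ".json"))
      if (file.exists(p))
        readings[[length(readings) + 1L]] <-
          read_reading(if (fmt == "json") p else file.path(sdir, nm), fmt = fmt)
    }
    sample_record(label = meta$label, concentration = meta$concentration,
                  readings = readings)
  })
}
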