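# File I/O for the trace / curve dialects used across the package.
# Traces travel as `time,value,unit` CSV with a JSON sidecar for calibration
# metadata; audio additionally as 16-bit PCM WAV.

#' Write a signal trace to CSV
#'
#' Writes the `time,value,unit` dialect plus an optional JSON sidecar
#' (`<path>.json`) carrying rate, unit, sensitivity and t0.
#'
#' @param trace A [signal_trace].
#' @param path Output CSV path.
#' @param sidecar Write the JSON metadata sidecar? Default TRUE.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "signal_trace"))
  df <- data.frame(time = trace_times(trace), value = trace$samples,
                   unit = trace$unit)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (isTRUE(sidecar)) {
    meta <- list(rate = trace$rate, unit = trace$unit,
                 sensitivity = trace$sensitivity, t0 = trace$t0)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a signal trace from CSV
#'
#' Reads the `time,value,unit` dialect written by [write_trace_csv()]. The
#' sampling rate is recovered from the JSON sidecar when present, otherwise
#' from the median time step.
#'
#' @param path CSV path.
#' @return A [signal_trace].
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    signal_trace(df$value, rate = meta$rate, unit = meta$unit,
                 sensitivity = meta$sensitivity, t0 = meta$t0)
  } else {
    dt <- stats::median(diff(df$time))
    unit <- if ("unit" %in% names(df)) as.character(df$unit[1]) else "dimensionless"
    signal_trace(df$value, rate = 1 / dt, unit = unit, t0 = df$time[1])
  }
}

#' Write a pressure trace as 16-bit PCM WAV
#'
#' Minimal single-channel RIFF/PCM writer. Samples are scaled by `scale`
#' (full scale = 1) and clipped to \[-1, 1\].
#'
#' @param trace A [signal_trace].
#' @param path Output path.
#' @param scale Value mapped to digital full scale; defaults to the trace's
#'   absolute maximum so the file uses the full dynamic range.
#' @return `path`, invisibly.
#' @export
write_wav <- function(trace, path, scale = max(abs(trace$samples))) {
  stopifnot(inherits(trace, "signal_trace"))
  if (scale <= 0) scale <- 1
  x <- pmax(-1, pmin(1, trace$samples / scale))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  rate <- as.integer(round(trace$rate))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV path.
#' @param unit Unit to stamp on the returned trace.
#' @return A [signal_trace] with samples in \[-1, 1\].
#' @export
read_wav <- function(path, unit = "dimensionless") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAV file", call. = FALSE)
  rate <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported", call. = FALSE)
      rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", n = sz / 2, size = 2,
                     signed = TRUE, endian = "little")
      return(signal_trace(pcm / 32767, rate = rate, unit = unit))
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
}

#' Write an intrusion curve to CSV
#'
#' Dialect: `pressure_MPa,cum_volume_ml_per_g` with a JSON sidecar for the
#' sample bulk density.
#'
#' @param curve An [intrusion_curve].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_intrusion_csv <- function(curve, path) {
  stopifnot(inherits(curve, "intrusion_curve"))
  df <- data.frame(pressure_MPa = curve$pressures,
                   cum_volume_ml_per_g = curve$cumulative_volume)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(sample_bulk_density = curve$sample_bulk_density,
         max_pressure = curve$max_pressure),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an intrusion curve from CSV
#'
#' @param path CSV path written by [write_intrusion_csv()].
#' @param sample_bulk_density Bulk density in kg/m^3; read from the sidecar
#'   when omitted.
#' @return An [intrusion_curve].
#' @export
read_intrusion_csv <- function(path, sample_bulk_density = NULL) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  if (is.null(sample_bulk_density)) {
    if (!file.exists(meta_path)) {
      stop("sample_bulk_density not given and no sidecar found", call. = FALSE)
    }
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    sample_bulk_density <- meta$sample_bulk_density
  }
  intrusion_curve(df$pressure_MPa, df$cum_volume_ml_per_g,
                  sample_bulk_density = sample_bulk_density)
}
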