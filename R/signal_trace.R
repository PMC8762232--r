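#' Uniformly sampled sensor time series
#'
#' A `signal_trace` holds a uniformly sampled sensor record together with the
#' metadata needed to interpret it physically: sampling rate, physical unit,
#' and (for microphone traces) the sensor sensitivity used for dB SPL
#' calibration.
#'
#' @param samples Numeric vector of samples; must be finite and of length
#'   at least 2.
#' @param rate Sampling rate in Hz (> 0).
#' @param unit One of `"mm"`, `"Pa"`, `"volts"`, `"dimensionless"`.
#' @param sensitivity Microphone sensitivity in dB re 1 V/Pa. Default -34,
#'   the sensitivity of a typical surgical condenser microphone.
#' @param t0 Time of the first sample in seconds.
#'
#' @return An object of class `signal_trace`: a list with elements
#'   `samples`, `rate`, `unit`, `sensitivity`, `t0`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), rate = 1000)
#' rms(tr)
#' @export
signal_trace <- function(samples, rate, unit = "dimensionless",
                         sensitivity = -34, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("signal_trace needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("signal_trace samples must be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar (Hz)", call. = FALSE)
  }
  unit <- match.arg(unit, c("mm", "Pa", "volts", "dimensionless"))
  structure(
    list(samples = samples, rate = rate, unit = unit,
         sensitivity = sensitivity, t0 = t0),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz (%.3f s), unit: %s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, x$unit))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Sample times of a trace
#'
#' @param trace A [signal_trace].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$rate
}

#' Duration of a trace in seconds
#' @param trace A [signal_trace].
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate

#' @export
plot.signal_trace <- function(x, ...) {
  plot(trace_times(x), x$samples, type = "l",
       xlab = "time (s)", ylab = x$unit, ...)
  invisible(x)
}
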