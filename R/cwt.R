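# Continuous wavelet transform with the analytic (complex) Morlet wavelet:
#   X_w(a, b) = |a|^{-1/2} \int x(t) conj(psi((t - b)/a)) dt
# computed per scale by FFT convolution. The pseudo-frequency map is
#   f(a) = f_c / (a * dt),  f_c = omega0 / (2 pi).

#' Continuous wavelet transform (complex Morlet)
#'
#' @param trace A [signal_trace].
#' @param scales Positive strictly increasing scales in samples, or `NULL`
#'   to derive them from `frequencies`.
#' @param frequencies Target pseudo-frequencies in Hz (used when `scales`
#'   is `NULL`); default a log grid from 4 periods in the trace up to
#'   Nyquist/2 with 64 voices.
#' @param wavelet Wavelet name; only `"morlet"` is supported.
#' @param omega0 Morlet center frequency parameter, default 6.
#' @return An object of class `scalogram`: list with `coefficients`
#'   (complex matrix, scales x time), `scales`, `frequencies` (Hz, one per
#'   scale, monotone decreasing in scale), `wavelet_name`.
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' tr <- signal_trace(sin(2 * pi * 2 * t), 100)
#' sc <- cwt(tr, frequencies = 2^seq(0, 4, length.out = 16))
#' sc$frequencies[which.max(rowMeans(Mod(sc$coefficients)))] # ~ 2 Hz
#' @export
cwt <- function(trace, scales = NULL, frequencies = NULL,
                wavelet = "morlet", omega0 = 6) {
  stopifnot(inherits(trace, "signal_trace"))
  if (!identical(wavelet, "morlet")) {
    stop(sprintf("unsupported wavelet '%s' (only 'morlet')", wavelet),
         call. = FALSE)
  }
  fc <- omega0 / (2 * pi)
  dt <- 1 / trace$rate
  if (is.null(scales)) {
    if (is.null(frequencies)) {
      fmin <- 4 / trace_duration(trace)
      fmax <- trace$rate / 4
      frequencies <- exp(seq(log(fmin), log(fmax), length.out = 64))
    }
    scales <- sort(fc / (frequencies * dt))
  }
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  scales <- sort(scales)
  x <- trace$samples
  n <- length(x)
  nfft <- stats::nextn(2L * n, 2L)
  xh <- stats::fft(c(x, rep(0, nfft - n)))
  w <- 2 * pi * (seq_len(nfft) - 1L) / nfft
  w[w >= pi] <- w[w >= pi] - 2 * pi   # angular frequency per sample
  coef <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  for (i in seq_along(scales)) {
    a <- scales[i]
    # analytic Morlet in the frequency domain (zero for w <= 0)
    psi_hat <- pi^(-1 / 4) * sqrt(2 * pi) * exp(-0.5 * (a * w - omega0)^2)
    psi_hat[w < 0] <- 0
    y <- stats::fft(xh * sqrt(a) * Conj(psi_hat), inverse = TRUE) / nfft
    coef[i, ] <- y[seq_len(n)]
  }
  structure(
    list(coefficients = coef, scales = scales,
         frequencies = fc / (scales * dt), wavelet_name = wavelet),
    class = "scalogram"
  )
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d scales x %d samples, %s wavelet, %.3g-%.3g Hz\n",
              nrow(x$coefficients), ncol(x$coefficients), x$wavelet_name,
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Ridge frequency of a scalogram
#'
#' Frequency of the scale with the largest mean coefficient magnitude.
#'
#' @param sc A `scalogram`.
#' @return Pseudo-frequency in Hz.
#' @export
scalogram_ridge <- function(sc) {
  stopifnot(inherits(sc, "scalogram"))
  sc$frequencies[which.max(rowMeans(Mod(sc$coefficients)))]
}
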