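# Calibration and characterization of sensor traces: RMS, dB SPL, STFT,
# fundamental detection, and rank-sum comparison of recording segments.

#' Root-mean-square amplitude
#'
#' RMS of the whole trace or of consecutive windows.
#'
#' @param trace A [signal_trace].
#' @param window Window length in seconds, or `NULL` (default) for the whole
#'   trace.
#' @return A single RMS value, or a numeric vector with one value per
#'   complete window.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 10 * seq(0, 1, 1e-3)), 1000)
#' rms(tr) # ~ 1/sqrt(2)
#' @export
rms <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$samples
  if (length(x) == 0L) stop("empty trace", call. = FALSE)
  if (is.null(window)) return(sqrt(mean(x^2)))
  if (window > trace_duration(trace)) {
    stop("window exceeds trace duration", call. = FALSE)
  }
  n <- max(1L, floor(window * trace$rate))
  k <- floor(length(x) / n)
  vapply(seq_len(k), function(i) {
    sqrt(mean(x[((i - 1L) * n + 1L):(i * n)]^2))
  }, numeric(1))
}

#' Sound pressure level in dB SPL
#'
#' `to_db_spl()` converts pressure in Pa to dB re 20 uPa;
#' `from_db_spl()` inverts it.
#'
#' @param pressure Pressure in Pa (> 0).
#' @param reference Reference pressure in Pa, default 20e-6.
#' @return Level in dB SPL.
#' @examples
#' to_db_spl(2)      # 100 dB
#' from_db_spl(64.0) # ~ 0.0317 Pa
#' @export
to_db_spl <- function(pressure, reference = 20e-6) {
  if (any(pressure <= 0)) stop("pressure must be positive", call. = FALSE)
  20 * log10(pressure / reference)
}

#' @rdname to_db_spl
#' @param level Level in dB SPL.
#' @export
from_db_spl <- function(level, reference = 20e-6) {
  reference * 10^(level / 20)
}

#' Calibrated pressure from a microphone voltage trace
#'
#' Applies the microphone sensitivity (dB re 1 V/Pa) to convert a voltage
#' trace to pascals, assuming a flat frequency response.
#'
#' @param trace A [signal_trace] with unit `"volts"`.
#' @return A [signal_trace] with unit `"Pa"`.
#' @export
calibrate_pressure <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$unit != "volts") stop("trace unit must be volts", call. = FALSE)
  sens_v_per_pa <- 10^(trace$sensitivity / 20)
  signal_trace(trace$samples / sens_v_per_pa, rate = trace$rate, unit = "Pa",
               sensitivity = trace$sensitivity, t0 = trace$t0)
}

#' Short-time Fourier transform spectrogram
#'
#' Frames the trace, windows each frame, and returns one-sided magnitude
#' spectra in dB re `reference_pressure`, clamped at a floor of -120 dB so
#' silence never produces -Inf.
#'
#' @param trace A [signal_trace].
#' @param window_length Frame length in samples.
#' @param hop Hop between frames in samples (> 0).
#' @param window `"hann"` or `"rect"`.
#' @param reference_pressure Reference for the dB scale (Pa), default 20e-6.
#' @param floor_db Clamp for the dB magnitudes, default -120.
#' @return An object of class `spectrogram`: list with `magnitudes_db`
#'   (frames x frequency matrix), `frequencies` (Hz), `times` (frame centers,
#'   s), `window_length`, `hop`, `reference_pressure`.
#' @export
stft <- function(trace, window_length = 256L, hop = window_length %/% 2L,
                 window = c("hann", "rect"), reference_pressure = 20e-6,
                 floor_db = -120) {
  stopifnot(inherits(trace, "signal_trace"))
  window <- match.arg(window)
  x <- trace$samples
  if (window_length > length(x)) {
    stop("window_length exceeds trace length", call. = FALSE)
  }
  if (hop <= 0) stop("hop must be positive", call. = FALSE)
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(window_length) - 1L) / (window_length - 1L))
  } else rep(1, window_length)
  starts <- seq(1L, length(x) - window_length + 1L, by = hop)
  nf <- window_length %/% 2L + 1L
  mags <- matrix(0, nrow = length(starts), ncol = nf)
  for (i in seq_along(starts)) {
    fr <- x[starts[i]:(starts[i] + window_length - 1L)] * w
    sp <- stats::fft(fr)[seq_len(nf)]
    # one-sided amplitude: double interior bins, normalise by window sum
    amp <- Mod(sp) / sum(w)
    if (nf > 2L) amp[2:(nf - 1L)] <- 2 * amp[2:(nf - 1L)]
    mags[i, ] <- amp
  }
  db <- 20 * log10(pmax(mags / reference_pressure, 10^(floor_db / 20)))
  structure(
    list(magnitudes_db = db,
         frequencies = (seq_len(nf) - 1L) * trace$rate / window_length,
         times = trace$t0 + (starts - 1L + window_length / 2) / trace$rate,
         window_length = window_length, hop = hop,
         reference_pressure = reference_pressure),
    class = "spectrogram"
  )
}

#' Per-frame signal energy recovered from a spectrogram
#'
#' Inverts the one-sided amplitude scaling and applies Parseval's theorem to
#' return the time-domain energy (sum of squares) of each analysis frame.
#' For a rectangular window this matches the framed signal's energy exactly.
#'
#' @param sg A `spectrogram` from [stft()].
#' @return Numeric vector, one energy per frame.
#' @export
frame_energies <- function(sg) {
  stopifnot(inherits(sg, "spectrogram"))
  nfft <- sg$window_length
  nf <- ncol(sg$magnitudes_db)
  amp <- 10^(sg$magnitudes_db / 20) * sg$reference_pressure
  mod <- amp * nfft
  if (nf > 2L) mod[, 2:(nf - 1L)] <- mod[, 2:(nf - 1L)] / 2
  weight <- rep(2, nf)
  weight[1] <- 1
  if (nfft %% 2L == 0L) weight[nf] <- 1
  as.numeric(mod^2 %*% weight) / nfft
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins, df = %.3g Hz\n",
              nrow(x$magnitudes_db), ncol(x$magnitudes_db),
              diff(x$frequencies[1:2])))
  invisible(x)
}

#' Dominant periodicity of a trace
#'
#' Detects the fundamental frequency via the highest non-zero-lag peak of
#' the autocorrelation. Returns `NA` for aperiodic (e.g. constant) input.
#' Pulse-synchronous vascular displacement traces yield their cardiac
#' fundamental, well below 20 Hz.
#'
#' @param trace A [signal_trace].
#' @param min_freq,max_freq Search band in Hz; the default upper bound is
#'   Nyquist/2 and the lower bound requires at least two periods in the
#'   trace.
#' @return Fundamental frequency in Hz, or `NA_real_` when no clear
#'   periodicity exists.
#' @export
detect_fundamental <- function(trace, min_freq = 2 / trace_duration(trace),
                               max_freq = trace$rate / 4) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$samples - mean(trace$samples)
  if (stats::sd(x) == 0) return(NA_real_)
  n <- length(x)
  ac <- stats::acf(x, lag.max = n - 1L, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lag_min <- max(2L, floor(trace$rate / max_freq))
  lag_max <- min(n - 1L, ceiling(trace$rate / min_freq))
  if (lag_min >= lag_max) return(NA_real_)
  # smooth signals keep the ACF near 1 at small lags; the period shows up
  # as the dominant peak past the first zero crossing
  zc <- which(ac[(lag_min + 1L):(lag_max + 1L)] < 0)[1]  # acf[1] is lag 0
  if (!is.na(zc)) lag_min <- lag_min + zc - 1L
  if (lag_min >= lag_max) return(NA_real_)
  seg <- ac[(lag_min + 1L):(lag_max + 1L)]
  k <- which.max(seg)
  if (seg[k] < 0.2) return(NA_real_)  # no credible periodicity
  lag <- lag_min + k - 1L
  # parabolic interpolation around the peak for sub-sample lag resolution
  if (lag > lag_min && lag < lag_max) {
    y1 <- ac[lag]; y2 <- ac[lag + 1L]; y3 <- ac[lag + 2L]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / denom * -1
  }
  trace$rate / lag
}

#' Rank-sum (Mann-Whitney U) comparison of two sample sets
#'
#' Two-sided Mann-Whitney U test. When both samples have at most
#' `exact_max` observations the p-value is computed by exact enumeration of
#' all rank assignments (ties handled naturally by the enumeration);
#' otherwise the normal approximation with tie correction is used.
#'
#' @param a,b Numeric vectors (nonempty).
#' @param exact_max Largest per-group size for exact enumeration, default 8.
#' @return A list with `statistic` (U for sample `a`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' compare_segments(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
compare_segments <- function(a, b, exact_max = 8L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both sample sets must be nonempty", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (all(c(a, b) == c(a, b)[1])) {
    return(list(statistic = u_a, p_value = 1, method = "degenerate"))
  }
  if (na <= exact_max && nb <= exact_max) {
    # enumerate U over all assignments of the pooled ranks to group a
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2L, function(ii) sum(r[ii]) - na * (na + 1) / 2)
    mu <- na * nb / 2
    p <- mean(abs(us - mu) >= abs(u_a - mu) - 1e-9)
    list(statistic = u_a, p_value = p, method = "exact")
  } else {
    n <- na + nb
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_corr))
    mu <- na * nb / 2
    z <- (u_a - mu) / sigma
    list(statistic = u_a, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal")
  }
}
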