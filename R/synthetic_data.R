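# Synthetic generators for every input the pipeline consumes: pulse-
# synchronous wall-displacement traces, band-limited tinnitus-like audio,
# four-microphone impedance-tube spectra, mercury intrusion curves, and
# periodic venous Doppler waveforms. Every generator takes an explicit seed;
# no global random state is touched.

#' Generator configuration
#'
#' Shared timing/noise settings for the synthetic generators. The defaults
#' mirror the measurement setup the package emulates: a cardiac period of
#' 1.46 s and a displacement-sensor sampling cycle of 1 ms (1 kHz).
#'
#' @param seed Integer seed; every generator is deterministic under it.
#' @param heart_period Cardiac period in seconds (> 0), default 1.46.
#' @param sample_rate_displacement Displacement sampling rate in Hz,
#'   default 1000.
#' @param sample_rate_audio Audio sampling rate in Hz, default 8000.
#' @param duration Trace duration in seconds; must cover at least two
#'   cardiac cycles. Default 10.
#' @param noise_sd Additive Gaussian noise s.d. in the signal's units.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, heart_period = 1.46,
                             sample_rate_displacement = 1000,
                             sample_rate_audio = 8000,
                             duration = 10, noise_sd = 0) {
  if (heart_period <= 0) stop("heart_period must be positive", call. = FALSE)
  if (sample_rate_displacement <= 0 || sample_rate_audio <= 0) {
    stop("sample rates must be positive", call. = FALSE)
  }
  if (duration < 2 * heart_period) {
    stop("duration must cover at least two cardiac cycles", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(
    list(seed = as.integer(seed), heart_period = heart_period,
         sample_rate_displacement = sample_rate_displacement,
         sample_rate_audio = sample_rate_audio,
         duration = duration, noise_sd = noise_sd),
    class = "generator_config"
  )
}

# run expr with a private RNG stream seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pulse-synchronous wall-displacement trace
#'
#' Emulates vascular-wall motion measured by a confocal laser displacement
#' sensor: a sum of `harmonics` harmonics of the cardiac fundamental
#' 1/`heart_period` with geometrically decaying amplitudes, scaled so the
#' median absolute excursion equals `median_amp`, plus Gaussian noise of
#' s.d. `config$noise_sd`.
#'
#' @param config A [generator_config].
#' @param median_amp Median absolute excursion in mm (> 0).
#' @param harmonics Number of harmonics (3-5 is typical), default 4.
#' @return A [signal_trace] in mm at `config$sample_rate_displacement`.
#' @examples
#' cfg <- generator_config(seed = 7, duration = 10)
#' tr <- gen_displacement_trace(cfg, median_amp = 0.092)
#' detect_fundamental(tr) # ~ 1/1.46 = 0.685 Hz
#' @export
gen_displacement_trace <- function(config, median_amp, harmonics = 4L) {
  stopifnot(inherits(config, "generator_config"))
  if (median_amp <= 0) stop("median_amp must be positive", call. = FALSE)
  if (config$duration <= 0) stop("duration must be positive", call. = FALSE)
  fs <- config$sample_rate_displacement
  t <- seq(0, config$duration - 1 / fs, by = 1 / fs)
  f0 <- 1 / config$heart_period
  h <- seq_len(max(1L, harmonics))
  base <- rowSums(sapply(h, function(k) {
    (0.5^(k - 1)) * sin(2 * pi * k * f0 * t + (k - 1) * pi / 3)
  }))
  base <- base * (median_amp / stats::median(abs(base)))
  samples <- if (config$noise_sd > 0) {
    base + with_seed(config$seed, stats::rnorm(length(t), 0, config$noise_sd))
  } else base
  signal_trace(samples, rate = fs, unit = "mm")
}

#' Band-limited tinnitus-like audio trace
#'
#' Pink-ish noise plus a low-frequency harmonic stack, brick-wall filtered
#' (via FFT with a smooth roll-off) so that all spectral energy lies below
#' `band_limit`, then scaled so the calibrated peak pressure equals
#' `peak_db_spl` re 20 uPa.
#'
#' @param config A [generator_config].
#' @param peak_db_spl Peak level in dB SPL; levels implying a pressure above
#'   200 Pa (140 dB SPL) are rejected.
#' @param band_limit Upper band edge in Hz (must not exceed Nyquist);
#'   default 2000, the band the tinnitus spectrum occupies.
#' @return A [signal_trace] in Pa at `config$sample_rate_audio`.
#' @export
gen_pt_audio <- function(config, peak_db_spl = 64, band_limit = 2000) {
  stopifnot(inherits(config, "generator_config"))
  fs <- config$sample_rate_audio
  if (band_limit > fs / 2) {
    stop("band_limit exceeds Nyquist frequency", call. = FALSE)
  }
  peak_pa <- from_db_spl(peak_db_spl)
  if (peak_pa > 200) {
    stop("peak_db_spl implies pressure above 200 Pa", call. = FALSE)
  }
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1) / fs
  f0 <- 1 / config$heart_period
  x <- with_seed(config$seed, {
    noise <- stats::rnorm(n)
    # cardiac amplitude modulation so the audio "undulates"
    am <- 1 + 0.6 * sin(2 * pi * f0 * t)
    stack <- rowSums(sapply(1:6, function(k) {
      (0.7^k) * sin(2 * pi * k * 60 * t + stats::runif(1, 0, 2 * pi))
    }))
    am * (noise + 2 * stack)
  })
  # zero everything above the band edge, with a raised-cosine roll-off
  # over the top 10% of the band to avoid ringing
  xh <- stats::fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)      # two-sided magnitude frequency
  gain <- rep(1, n)
  lo <- 0.9 * band_limit
  ramp <- freq > lo & freq < band_limit
  gain[ramp] <- 0.5 * (1 + cos(pi * (freq[ramp] - lo) / (band_limit - lo)))
  gain[freq >= band_limit] <- 0
  x <- Re(stats::fft(xh * gain, inverse = TRUE)) / n
  x <- x * (peak_pa / max(abs(x)))
  signal_trace(x, rate = fs, unit = "Pa")
}

#' Four-microphone impedance-tube pressure spectra
#'
#' Simulates the plane-wave field of a four-microphone impedance tube with
#' an anechoic termination around a specimen described by a symmetric
#' reciprocal transfer matrix. Intended as a round-trip fixture: feeding the
#' result to [tube_transfer_matrix()] then [transmission_loss()] recovers
#' the specimen's transmission loss.
#'
#' @param material A [material_spec], or `NULL` for the empty tube. When the
#'   material carries a `tl_curve`, a minimum-phase symmetric matrix
#'   matching that curve is used; otherwise the physical layer matrix from
#'   thickness, density and elastic moduli.
#' @param freqs Frequencies in Hz (all > 0).
#' @param medium An [acoustic_medium] for the air in the tube.
#' @param spacing Microphone spacing in m, default 0.05.
#' @param gap Distance from the inner microphones to the specimen faces in
#'   m, default 0.05.
#' @return An object of class `tube_signals`: list of four complex pressure
#'   spectra `p1..p4` (upstream pair, downstream pair), plus geometry and
#'   medium needed for the reduction.
#' @export
gen_tube_signals <- function(material, freqs, medium = acoustic_medium(),
                             spacing = 0.05, gap = 0.05) {
  if (any(freqs <= 0)) stop("frequencies must be positive", call. = FALSE)
  tm <- if (is.null(material)) {
    identity_transfer_matrix(freqs, medium)
  } else {
    material_transfer_matrix(material, freqs, medium)
  }
  rc <- medium$air_density * medium$sound_speed
  k <- 2 * pi * freqs / medium$sound_speed
  # downstream (anechoic): forward wave of unit amplitude at the back face
  c_amp <- 1 + 0i
  p_b <- c_amp
  u_b <- c_amp / rc
  # front-face state through the specimen matrix
  p_f <- tm$A * p_b + tm$B * u_b
  u_f <- tm$C * p_b + tm$D * u_b
  # upstream decomposition p(x) = a e^{-jkx} + b e^{+jkx}, x = 0 at front face
  a_amp <- (p_f + rc * u_f) / 2
  b_amp <- (p_f - rc * u_f) / 2
  x1 <- -(gap + spacing); x2 <- -gap
  x3 <- gap; x4 <- gap + spacing    # measured from the back face
  p1 <- a_amp * exp(-1i * k * x1) + b_amp * exp(1i * k * x1)
  p2 <- a_amp * exp(-1i * k * x2) + b_amp * exp(1i * k * x2)
  p3 <- c_amp * exp(-1i * k * x3)
  p4 <- c_amp * exp(-1i * k * x4)
  structure(
    list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, freqs = freqs,
         spacing = spacing, gap = gap, medium = medium),
    class = "tube_signals"
  )
}

#' Mercury intrusion curve from a known pore-size distribution
#'
#' Builds a synthetic porosimetry record: pore diameters drawn from a
#' log-normal mixture are mapped to intrusion pressures by the Washburn
#' relation, and the cumulative intruded volume reaches
#' `porosity / bulk_density` (volume per gram) at the maximum pressure.
#'
#' @param distribution List with `median_um` (vector of component medians,
#'   micrometres), `sdlog` (vector), `weights` (vector summing to 1).
#' @param porosity Void fraction in (0, 1).
#' @param bulk_density Sample bulk density in kg/m^3.
#' @param params A [mercury_params].
#' @param n_points Number of pressure points, default 200.
#' @return An [intrusion_curve]. A warning is raised when the distribution
#'   support extends beyond the 0.003-950 um detection range.
#' @examples
#' curve <- gen_intrusion_curve(list(median_um = 100, sdlog = 0.5,
#'                                   weights = 1),
#'                              porosity = 0.967, bulk_density = 34.2)
#' porosity(curve) # ~ 96.7
#' @export
gen_intrusion_curve <- function(distribution, porosity, bulk_density,
                                params = mercury_params(), n_points = 200L) {
  if (porosity <= 0 || porosity >= 1) {
    stop("porosity must lie in (0, 1)", call. = FALSE)
  }
  med <- distribution$median_um
  sdl <- distribution$sdlog
  wts <- distribution$weights / sum(distribution$weights)
  # effective support: medians +/- 4 sd on the log scale
  lo <- min(med * exp(-4 * sdl)); hi <- max(med * exp(4 * sdl))
  if (lo < 0.003 || hi > 950) {
    warning("pore-size support extends beyond the 0.003-950 um detection range")
  }
  total_v <- porosity / (bulk_density / 1000)  # ml/g (density in g/cm^3)
  # pressure grid spanning the Washburn image of the support
  d_lo <- max(lo / 2, 0.003) * 1e-6
  d_hi <- min(hi * 2, 950) * 1e-6
  p_hi <- min(washburn_pressure(d_lo, params), 400e6)
  p_lo <- washburn_pressure(d_hi, params)
  pressures <- exp(seq(log(p_lo), log(p_hi), length.out = n_points))
  diam_um <- washburn_diameter(pressures, params) * 1e6
  # volume intruded at pressure P = volume in pores with diameter >= d(P)
  cdf_above <- vapply(diam_um, function(d) {
    sum(wts * stats::pnorm((log(d) - log(med)) / sdl, lower.tail = FALSE))
  }, numeric(1))
  intrusion_curve(pressures / 1e6, total_v * cdf_above,
                  sample_bulk_density = bulk_density)
}

#' Periodic venous Doppler time-velocity waveform
#'
#' Raised-cosine pulsatile waveform on a baseline:
#' `v(t) = v_mean * (1 - pulsatility + pulsatility * (1 - cos(2 pi t / T)))`,
#' which has cycle mean `v_mean`, minimum `v_mean * (1 - pulsatility)` and
#' maximum `v_mean * (1 + pulsatility)`.
#'
#' @param config A [generator_config].
#' @param mean_velocity Cycle-mean velocity in m/s (> 0).
#' @param pulsatility Fractional modulation depth in \[0, 1).
#' @return A [signal_trace] (unit `dimensionless`, values in m/s) at
#'   `config$sample_rate_displacement`.
#' @export
gen_doppler_waveform <- function(config, mean_velocity, pulsatility = 0.5) {
  stopifnot(inherits(config, "generator_config"))
  if (mean_velocity <= 0) stop("mean_velocity must be positive", call. = FALSE)
  if (pulsatility < 0 || pulsatility >= 1) {
    stop("pulsatility must lie in [0, 1)", call. = FALSE)
  }
  fs <- config$sample_rate_displacement
  t <- seq(0, config$duration - 1 / fs, by = 1 / fs)
  v <- mean_velocity *
    (1 - pulsatility + pulsatility * (1 - cos(2 * pi * t / config$heart_period)))
  signal_trace(v, rate = fs, unit = "dimensionless")
}
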