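# Impedance-tube acoustics for grafts and biomaterials: transfer-matrix
# transmission loss, absorption factor, octave-band averaging, mass-law
# estimates and multilayer composite insulation.

#' Octave-band center-frequency sets
#'
#' `absorption6` is the 6-band set used for absorption averaging,
#' `tl13` the 13-band one-third-octave set used for transmission loss.
#'
#' @param band_set `"absorption6"` or `"tl13"`.
#' @return Numeric vector of center frequencies in Hz.
#' @export
band_centers <- function(band_set = c("tl13", "absorption6")) {
  band_set <- match.arg(band_set)
  switch(band_set,
    absorption6 = c(125, 250, 500, 1000, 2000, 4000),
    tl13 = c(125, 160, 200, 250, 315, 400, 500, 630, 800,
             1000, 1250, 1600, 2000))
}

#' Values on a named octave-band set
#'
#' @param values Numeric values, one per band center.
#' @param band_set `"absorption6"`, `"tl13"` or `"custom"`.
#' @param centers Band centers in Hz; derived from `band_set` unless
#'   `band_set = "custom"`.
#' @return An object of class `band_spectrum`.
#' @export
band_spectrum <- function(values, band_set = "tl13", centers = NULL) {
  if (band_set != "custom") {
    centers <- band_centers(band_set)
  } else if (is.null(centers)) {
    stop("custom band_spectrum needs explicit centers", call. = FALSE)
  }
  if (length(values) != length(centers)) {
    stop("values and centers differ in length", call. = FALSE)
  }
  structure(list(centers = centers, values = as.numeric(values),
                 band_set = band_set),
            class = "band_spectrum")
}

#' @export
print.band_spectrum <- function(x, ...) {
  cat(sprintf("<band_spectrum> %s (%d bands), mean %.3g\n", x$band_set,
              length(x$centers), mean(x$values)))
  invisible(x)
}

#' Band values and band average of a fine-grid spectrum
#'
#' Interpolates a fine-grid spectrum to the centers of a named band set
#' (linearly on a log-frequency axis) and averages arithmetically. Values
#' exactly on a center are taken as-is; a center outside the covered range
#' is an error naming the center.
#'
#' @param freqs Frequencies of the fine grid (Hz), or a `band_spectrum` /
#'   `tl_spectrum` (then `values` is ignored).
#' @param values Spectrum values on `freqs`.
#' @param band_set Target band set, default `"tl13"`.
#' @return `band_values()` returns a [band_spectrum]; `band_average()` the
#'   arithmetic mean over the centers.
#' @export
band_values <- function(freqs, values = NULL, band_set = "tl13") {
  if (inherits(freqs, "tl_spectrum")) {
    values <- freqs$tl; freqs <- freqs$freqs
  } else if (inherits(freqs, "band_spectrum")) {
    values <- freqs$values; freqs <- freqs$centers
  }
  centers <- band_centers(band_set)
  out <- numeric(length(centers))
  for (i in seq_along(centers)) {
    fc <- centers[i]
    j <- which(abs(freqs - fc) < 1e-9)
    if (length(j) > 0) { out[i] <- values[j[1]]; next }
    if (fc < min(freqs) || fc > max(freqs)) {
      stop(sprintf("spectrum does not cover band center %g Hz", fc),
           call. = FALSE)
    }
    out[i] <- stats::approx(log(freqs), values, xout = log(fc))$y
  }
  band_spectrum(out, band_set)
}

#' @rdname band_values
#' @export
band_average <- function(freqs, values = NULL, band_set = "tl13") {
  mean(band_values(freqs, values, band_set)$values)
}

#' Biomaterial layer specification
#'
#' One reconstruction material: geometry, bulk density and elastic moduli,
#' with optional measured transmission-loss / absorption curves.
#'
#' @param name Material name.
#' @param thickness Thickness in m (> 0).
#' @param density Bulk density in kg/m^3 (> 0).
#' @param diameter Specimen diameter in m (0.020 or 0.030 for the tube).
#' @param youngs_modulus Young's modulus in Pa.
#' @param poisson_ratio Poisson's ratio in (0, 0.5).
#' @param tl_curve,absorption_curve Optional [band_spectrum] of measured
#'   values.
#' @param model Acoustic layer model: `"elastic"` (transfer matrix from the
#'   longitudinal sound speed), `"limp"` (limp-mass layer), or
#'   `"configured_tl"` (synthetic matrix matching `tl_curve`).
#' @param sound_speed Optional explicit layer sound speed in m/s, overriding
#'   the value derived from the elastic moduli.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, thickness, density, diameter = 0.020,
                          youngs_modulus = NA_real_, poisson_ratio = 0.3,
                          tl_curve = NULL, absorption_curve = NULL,
                          model = c("elastic", "limp", "configured_tl"),
                          sound_speed = NULL) {
  if (thickness <= 0 || density <= 0) {
    stop("thickness and density must be positive", call. = FALSE)
  }
  if (!is.na(poisson_ratio) && (poisson_ratio <= 0 || poisson_ratio >= 0.5)) {
    stop("poisson_ratio must lie in (0, 0.5)", call. = FALSE)
  }
  structure(
    list(name = name, thickness = thickness, density = density,
         diameter = diameter, youngs_modulus = youngs_modulus,
         poisson_ratio = poisson_ratio, tl_curve = tl_curve,
         absorption_curve = absorption_curve, model = match.arg(model),
         sound_speed = sound_speed),
    class = "material_spec"
  )
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: %.1f mm, %.1f kg/m^3 (%.3g kg/m^2)\n",
              x$name, x$thickness * 1000, x$density, areal_density(x)))
  invisible(x)
}

#' Areal density of a layer
#'
#' Mass per unit area, density x thickness: the quantity that governs
#' mass-law sound insulation.
#'
#' @param m A [material_spec].
#' @return Areal density in kg/m^2.
#' @examples
#' bw <- material_spec("bone wax", 0.0033, 945.3)
#' areal_density(bw) # ~ 3.12 kg/m^2
#' @export
areal_density <- function(m) {
  stopifnot(inherits(m, "material_spec"))
  m$density * m$thickness
}

#' Longitudinal sound speed of a layer
#'
#' Thin-solid longitudinal wave speed
#' `sqrt(E (1 - nu) / (rho (1 + nu) (1 - 2 nu)))`, unless the layer
#' configures `sound_speed` directly.
#'
#' @param m A [material_spec].
#' @return Sound speed in m/s.
#' @export
layer_sound_speed <- function(m) {
  stopifnot(inherits(m, "material_spec"))
  if (!is.null(m$sound_speed)) return(m$sound_speed)
  if (is.na(m$youngs_modulus)) {
    stop(sprintf("layer '%s' has neither sound_speed nor youngs_modulus",
                 m$name), call. = FALSE)
  }
  e <- m$youngs_modulus; nu <- m$poisson_ratio
  sqrt(e * (1 - nu) / (m$density * (1 + nu) * (1 - 2 * nu)))
}

#' Per-frequency acoustic transfer matrices
#'
#' Container for the 2x2 plane-wave transfer matrices relating the acoustic
#' state (pressure, particle velocity) upstream of a specimen to the state
#' downstream, per frequency, together with the tube medium and areas.
#'
#' @param freqs Strictly increasing positive frequencies (Hz).
#' @param A,B,C,D Complex matrix elements per frequency.
#' @param medium An [acoustic_medium].
#' @param inlet_area,outlet_area Tube cross-sections in m^2.
#' @return An object of class `transfer_matrix_spectrum`.
#' @export
transfer_matrix_spectrum <- function(freqs, A, B, C, D,
                                     medium = acoustic_medium(),
                                     inlet_area = 1, outlet_area = 1) {
  if (any(freqs <= 0) || is.unsorted(freqs, strictly = TRUE)) {
    stop("freqs must be positive and strictly increasing", call. = FALSE)
  }
  if (inlet_area <= 0 || outlet_area <= 0) {
    stop("areas must be positive", call. = FALSE)
  }
  structure(
    list(freqs = freqs, A = A, B = B, C = C, D = D, medium = medium,
         inlet_area = inlet_area, outlet_area = outlet_area),
    class = "transfer_matrix_spectrum"
  )
}

identity_transfer_matrix <- function(freqs, medium = acoustic_medium()) {
  n <- length(freqs)
  transfer_matrix_spectrum(freqs, rep(1 + 0i, n), rep(0i, n), rep(0i, n),
                           rep(1 + 0i, n), medium)
}

# transfer matrix of one homogeneous layer (elastic / limp / configured-TL)
material_transfer_matrix <- function(m, freqs, medium = acoustic_medium()) {
  stopifnot(inherits(m, "material_spec"))
  n <- length(freqs)
  rc <- medium$air_density * medium$sound_speed
  if (m$model == "configured_tl") {
    if (is.null(m$tl_curve)) {
      stop(sprintf("layer '%s' uses configured_tl but has no tl_curve",
                   m$name), call. = FALSE)
    }
    tl <- stats::approx(log(m$tl_curve$centers), m$tl_curve$values,
                        xout = log(freqs), rule = 2)$y
    # symmetric reciprocal matrix with A = D = 1, C = 0:
    # TL = 20 log10(0.5 |2 + B/(rho c)|)  =>  B real, B = rc (2*10^(TL/20) - 2)
    B <- rc * (2 * 10^(tl / 20) - 2) + 0i
    transfer_matrix_spectrum(freqs, rep(1 + 0i, n), B, rep(0i, n),
                             rep(1 + 0i, n), medium)
  } else if (m$model == "limp") {
    B <- 1i * 2 * pi * freqs * areal_density(m)
    transfer_matrix_spectrum(freqs, rep(1 + 0i, n), B, rep(0i, n),
                             rep(1 + 0i, n), medium)
  } else {
    cl <- layer_sound_speed(m)
    z <- m$density * cl
    kd <- 2 * pi * freqs / cl * m$thickness
    transfer_matrix_spectrum(freqs, cos(kd) + 0i, 1i * z * sin(kd),
                             1i * sin(kd) / z, cos(kd) + 0i, medium)
  }
}

#' Transmission loss from a transfer-matrix spectrum
#'
#' Evaluates the transfer-matrix transmission loss
#' `TL = 20 log10( (1/2) |A + B/(rho c) + rho c C + D| ) +
#'  10 log10(S_i / S_o)` per frequency. Frequencies where the matrix sum is
#' numerically zero are reported as `NA` with a warning.
#'
#' @param tm A [transfer_matrix_spectrum].
#' @return An object of class `tl_spectrum`: list with `freqs` and `tl`
#'   (dB). Use [band_values()] / [band_average()] for band reduction.
#' @examples
#' tm <- transfer_matrix_spectrum(c(500, 1000), c(1, 1), c(0, 0),
#'                                c(0, 0), c(1, 1))
#' transmission_loss(tm)$tl # 0 dB
#' @export
transmission_loss <- function(tm) {
  stopifnot(inherits(tm, "transfer_matrix_spectrum"))
  rc <- tm$medium$air_density * tm$medium$sound_speed
  s <- tm$A + tm$B / rc + rc * tm$C + tm$D
  bad <- Mod(s) < 1e-300
  if (any(bad)) {
    warning(sprintf("singular transfer matrix at %d frequencies", sum(bad)))
  }
  tl <- rep(NA_real_, length(s))
  tl[!bad] <- 20 * log10(0.5 * Mod(s[!bad])) +
    10 * log10(tm$inlet_area / tm$outlet_area)
  structure(list(freqs = tm$freqs, tl = tl), class = "tl_spectrum")
}

#' @export
print.tl_spectrum <- function(x, ...) {
  cat(sprintf("<tl_spectrum> %d frequencies, TL %.2f-%.2f dB\n",
              length(x$freqs), min(x$tl, na.rm = TRUE),
              max(x$tl, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.tl_spectrum <- function(x, ...) {
  plot(x$freqs, x$tl, type = "l", log = "x", xlab = "frequency (Hz)",
       ylab = "transmission loss (dB)", ...)
  invisible(x)
}

#' Transfer matrix from four-microphone tube spectra
#'
#' Reduces the four complex pressure spectra of an impedance-tube
#' measurement to a per-frequency transfer matrix, assuming a symmetric
#' reciprocal specimen (`A = D`, `AD - BC = 1`), the one-load variant of
#' the transfer-matrix method.
#'
#' @param sig A `tube_signals` object from [gen_tube_signals()].
#' @return A [transfer_matrix_spectrum].
#' @export
tube_transfer_matrix <- function(sig) {
  stopifnot(inherits(sig, "tube_signals"))
  rc <- sig$medium$air_density * sig$medium$sound_speed
  k <- 2 * pi * sig$freqs / sig$medium$sound_speed
  x1 <- -(sig$gap + sig$spacing); x2 <- -sig$gap
  x3 <- sig$gap; x4 <- sig$gap + sig$spacing
  dec <- function(pa, pb, xa, xb) {
    det <- exp(-1i * k * xa) * exp(1i * k * xb) -
      exp(-1i * k * xb) * exp(1i * k * xa)
    a <- (pa * exp(1i * k * xb) - pb * exp(1i * k * xa)) / det
    b <- (pb * exp(-1i * k * xa) - pa * exp(-1i * k * xb)) / det
    list(fwd = a, bwd = b)
  }
  up <- dec(sig$p1, sig$p2, x1, x2)
  dn <- dec(sig$p3, sig$p4, x3, x4)
  p_f <- up$fwd + up$bwd
  u_f <- (up$fwd - up$bwd) / rc
  p_b <- dn$fwd + dn$bwd
  u_b <- (dn$fwd - dn$bwd) / rc
  A <- (p_b * u_b + p_f * u_f) / (p_f * u_b + p_b * u_f)
  B <- (p_f - A * p_b) / u_b
  C <- (u_f - A * u_b) / p_b
  transfer_matrix_spectrum(sig$freqs, A, B, C, A, sig$medium)
}

#' Sound absorption factor from reflection coefficients
#'
#' `alpha = 1 - r` with `r` the (power) reflection coefficient in \[0, 1\],
#' so `alpha` is the fraction of incident energy not reflected (absorbed
#' plus transmitted).
#'
#' @param r Reflection coefficients, one per band center, each in \[0, 1\].
#' @param band_set Band set of the result, default `"absorption6"`.
#' @return A [band_spectrum] of absorption factors.
#' @examples
#' mean(absorption_factor(rep(0.829, 6))$values) # 0.171
#' @export
absorption_factor <- function(r, band_set = "absorption6") {
  if (any(r < 0 | r > 1)) {
    stop("reflection coefficients must lie in [0, 1]", call. = FALSE)
  }
  band_spectrum(1 - r, band_set)
}

#' Normal-incidence mass-law transmission loss
#'
#' `TL = 10 log10(1 + (pi f m / (rho c))^2)` for a limp layer of areal
#' density `m`; monotone increasing in both `f` and `m`, approaching
#' 6.02 dB per doubling of either.
#'
#' @param areal_density Areal density m in kg/m^2.
#' @param f Frequency in Hz.
#' @param rho_air Air density in kg/m^3, default 1.139.
#' @param c Sound speed in m/s, default 340.
#' @return Transmission loss in dB.
#' @examples
#' mass_law_tl(3.119, 1000) # ~ 28.1 dB
#' @export
mass_law_tl <- function(areal_density, f, rho_air = 1.139, c = 340) {
  if (any(areal_density < 0) || any(f <= 0) || rho_air <= 0 || c <= 0) {
    stop("arguments must be positive", call. = FALSE)
  }
  10 * log10(1 + (pi * f * areal_density / (rho_air * c))^2)
}

#' Density estimated from a measured transmission-loss curve
#'
#' Least-squares inversion of the mass law for the areal density that best
#' reproduces a measured TL curve, divided by the specimen thickness. A
#' large fit residual (e.g. a stiffness-controlled or resonant curve) or a
#' near-zero estimate flags the result as low confidence.
#'
#' @param tl_curve A [band_spectrum] on the `tl13` set.
#' @param thickness Specimen thickness in m.
#' @param rho_air,c Air properties for the mass law.
#' @return List with `density` (kg/m^3), `areal_density` (kg/m^2),
#'   `residual_rms` (dB) and `low_confidence` (logical).
#' @export
estimate_density_from_tl <- function(tl_curve, thickness,
                                     rho_air = 1.139, c = 340) {
  stopifnot(inherits(tl_curve, "band_spectrum"))
  if (thickness <= 0) stop("thickness must be positive", call. = FALSE)
  f <- tl_curve$centers
  tl <- tl_curve$values
  obj <- function(log_m) {
    sum((mass_law_tl(exp(log_m), f, rho_air, c) - tl)^2)
  }
  fit <- stats::optimize(obj, interval = log(c(1e-8, 1e4)))
  m <- exp(fit$minimum)
  resid <- sqrt(fit$objective / length(f))
  if (max(tl) < 0.5) m <- 0  # degenerate: essentially no insulation
  list(density = m / thickness, areal_density = m, residual_rms = resid,
       low_confidence = resid > 3 || m < 1e-6 || is.unsorted(tl))
}

#' Ordered multilayer reconstruction stack
#'
#' @param layers List of [material_spec] layers, outermost first.
#' @param air_gaps Air-gap thicknesses in m between consecutive layers
#'   (length `length(layers) - 1`), default none.
#' @return An object of class `reconstruction_stack`.
#' @export
reconstruction_stack <- function(layers, air_gaps = NULL) {
  if (length(layers) < 1L) stop("need at least one layer", call. = FALSE)
  if (!all(vapply(layers, inherits, logical(1), "material_spec"))) {
    stop("layers must be material_spec objects", call. = FALSE)
  }
  if (is.null(air_gaps)) air_gaps <- rep(0, length(layers) - 1L)
  if (length(air_gaps) != length(layers) - 1L) {
    stop("need one air gap per layer interface", call. = FALSE)
  }
  if (any(air_gaps < 0)) stop("air gaps must be non-negative", call. = FALSE)
  structure(list(layers = layers, air_gaps = air_gaps),
            class = "reconstruction_stack")
}

#' @export
print.reconstruction_stack <- function(x, ...) {
  cat(sprintf("<reconstruction_stack> %d layers: %s\n", length(x$layers),
              paste(vapply(x$layers, `[[`, character(1), "name"),
                    collapse = " | ")))
  invisible(x)
}

air_gap_matrix <- function(gap, freqs, medium) {
  rc <- medium$air_density * medium$sound_speed
  kd <- 2 * pi * freqs / medium$sound_speed * gap
  list(A = cos(kd) + 0i, B = 1i * rc * sin(kd),
       C = 1i * sin(kd) / rc, D = cos(kd) + 0i)
}

#' Composite transmission loss of a multilayer stack
#'
#' Cascades the per-layer 2x2 acoustic transfer matrices (with air-gap
#' layers between them) and evaluates [transmission_loss()]. A stack of
#' lossless air layers gives 0 dB at every frequency.
#'
#' @param stack A [reconstruction_stack].
#' @param freqs Frequencies in Hz.
#' @param medium An [acoustic_medium].
#' @return A `tl_spectrum`.
#' @export
composite_stack_tl <- function(stack, freqs, medium = acoustic_medium()) {
  stopifnot(inherits(stack, "reconstruction_stack"))
  n <- length(freqs)
  acc <- list(A = rep(1 + 0i, n), B = rep(0i, n),
              C = rep(0i, n), D = rep(1 + 0i, n))
  mul <- function(m1, m2) {
    list(A = m1$A * m2$A + m1$B * m2$C, B = m1$A * m2$B + m1$B * m2$D,
         C = m1$C * m2$A + m1$D * m2$C, D = m1$C * m2$B + m1$D * m2$D)
  }
  for (i in seq_along(stack$layers)) {
    lt <- material_transfer_matrix(stack$layers[[i]], freqs, medium)
    acc <- mul(acc, list(A = lt$A, B = lt$B, C = lt$C, D = lt$D))
    if (i < length(stack$layers) && stack$air_gaps[i] > 0) {
      acc <- mul(acc, air_gap_matrix(stack$air_gaps[i], freqs, medium))
    }
  }
  transmission_loss(transfer_matrix_spectrum(freqs, acc$A, acc$B, acc$C,
                                             acc$D, medium))
}

#' Load a material library from YAML
#'
#' Reads a YAML file of material definitions (the package ships one with
#' the measured graft/biomaterial properties at
#' `system.file("extdata", "materials.yaml", package = "ptinsulate")`).
#'
#' @param path YAML path.
#' @return Named list of [material_spec] objects.
#' @export
read_material_library <- function(path = system.file("extdata",
                                                     "materials.yaml",
                                                     package = "ptinsulate")) {
  raw <- yaml::read_yaml(path)
  mats <- lapply(raw, function(m) {
    tlc <- if (!is.null(m$average_tl_db)) {
      band_spectrum(rep(m$average_tl_db, 13), "tl13")
    } else NULL
    material_spec(
      name = m$name, thickness = m$thickness_mm / 1000,
      density = m$density_kg_m3, diameter = m$diameter_mm / 1000,
      youngs_modulus = m$youngs_modulus_mpa * 1e6,
      poisson_ratio = m$poisson_ratio, tl_curve = tlc
    )
  })
  stats::setNames(mats, vapply(raw, `[[`, character(1), "name"))
}
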