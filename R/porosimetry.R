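# Mercury-intrusion porosimetry reduction: Washburn pressure <-> pore-size
# inversion, porosity, 4V/A mean pore diameter, and pore-size distribution.

#' Mercury intrusion parameters
#'
#' Surface tension and contact angle of mercury. The contact angle must
#' exceed 90 degrees (cos(theta) < 0) for the Washburn inversion to yield
#' positive diameters; the defaults reproduce a 0.003 um detection floor at
#' the instrument's 400 MPa pressure ceiling.
#'
#' @param surface_tension Mercury surface tension in N/m, default 0.485.
#' @param contact_angle Contact angle in degrees (> 90), default 130.
#' @return An object of class `mercury_params`.
#' @export
mercury_params <- function(surface_tension = 0.485, contact_angle = 130) {
  if (surface_tension <= 0) {
    stop("surface_tension must be positive", call. = FALSE)
  }
  if (contact_angle <= 90) {
    stop("contact_angle must exceed 90 degrees", call. = FALSE)
  }
  structure(list(surface_tension = surface_tension,
                 contact_angle = contact_angle),
            class = "mercury_params")
}

#' Washburn pore diameter from intrusion pressure
#'
#' `d = -4 sigma cos(theta) / P`: the diameter of the smallest pore mercury
#' has entered at pressure `P`. Positive because cos(theta) < 0 for
#' non-wetting mercury; strictly decreasing in `P`.
#'
#' @param P Intrusion pressure in Pa (> 0).
#' @param params A [mercury_params].
#' @return Pore diameter in m.
#' @examples
#' washburn_diameter(400e6) # ~ 3.1e-9 m, the instrument detection floor
#' @export
washburn_diameter <- function(P, params = mercury_params()) {
  stopifnot(inherits(params, "mercury_params"))
  if (any(P <= 0)) stop("pressure must be positive", call. = FALSE)
  ct <- cos(params$contact_angle * pi / 180)
  -4 * params$surface_tension * ct / P
}

#' @rdname washburn_diameter
#' @param d Pore diameter in m.
#' @return `washburn_pressure()` returns the intrusion pressure in Pa.
#' @export
washburn_pressure <- function(d, params = mercury_params()) {
  stopifnot(inherits(params, "mercury_params"))
  if (any(d <= 0)) stop("diameter must be positive", call. = FALSE)
  ct <- cos(params$contact_angle * pi / 180)
  -4 * params$surface_tension * ct / d
}

#' Mercury intrusion record
#'
#' @param pressures Strictly increasing intrusion pressures in MPa, all in
#'   (0, `max_pressure`\].
#' @param cumulative_volume Non-decreasing cumulative intruded volume in
#'   ml/g.
#' @param sample_bulk_density Sample bulk density in kg/m^3.
#' @param max_pressure Instrument ceiling in MPa, default 400.
#' @return An object of class `intrusion_curve`.
#' @export
intrusion_curve <- function(pressures, cumulative_volume,
                            sample_bulk_density, max_pressure = 400) {
  if (any(pressures <= 0) || any(pressures > max_pressure)) {
    stop(sprintf("pressures must lie in (0, %g] MPa", max_pressure),
         call. = FALSE)
  }
  if (is.unsorted(pressures, strictly = TRUE)) {
    stop("pressures must be strictly increasing", call. = FALSE)
  }
  dv <- diff(cumulative_volume)
  if (any(dv < -1e-12)) {
    stop(sprintf("cumulative volume decreases at index %d",
                 which(dv < -1e-12)[1] + 1L), call. = FALSE)
  }
  structure(
    list(pressures = pressures, cumulative_volume = cumulative_volume,
         sample_bulk_density = sample_bulk_density,
         max_pressure = max_pressure),
    class = "intrusion_curve"
  )
}

#' @export
print.intrusion_curve <- function(x, ...) {
  cat(sprintf(
    "<intrusion_curve> %d points, %.3g-%.3g MPa, V_total %.4g ml/g\n",
    length(x$pressures), min(x$pressures), max(x$pressures),
    max(x$cumulative_volume)))
  invisible(x)
}

#' Porosity from an intrusion curve
#'
#' Total intruded volume times bulk density, in percent: the fraction of
#' the bulk sample volume occupied by intrudable pores.
#'
#' @param curve An [intrusion_curve], or the total intruded volume in ml/g
#'   (then `bulk_density` must be given).
#' @param bulk_density Bulk density in kg/m^3 (only when `curve` is a bare
#'   volume).
#' @return Porosity in percent.
#' @examples
#' porosity(28.28, 34.2) # 96.7
#' @export
porosity <- function(curve, bulk_density = NULL) {
  if (inherits(curve, "intrusion_curve")) {
    v_total <- max(curve$cumulative_volume)
    bulk_density <- curve$sample_bulk_density
  } else {
    v_total <- curve
    if (is.null(bulk_density)) {
      stop("bulk_density required with a bare volume", call. = FALSE)
    }
  }
  phi <- v_total * (bulk_density / 1000)  # ml/g x g/cm^3
  if (phi > 1 + 1e-9) {
    stop(sprintf(
      "intruded volume x bulk density = %.3f > 1: inconsistent inputs",
      phi), call. = FALSE)
  }
  100 * min(phi, 1)
}

#' Mean pore diameter by the 4V/A convention
#'
#' `4 V / A` with `V` the total intruded volume and `A` the total pore
#' area, the cylindrical-pore mean diameter an intrusion porosimeter
#' reports.
#'
#' @param v_total Total intruded volume in ml/g.
#' @param a_total Total pore area in m^2/g (> 0).
#' @return Mean pore diameter in m.
#' @examples
#' mean_pore_diameter_4v_a(28.28, 0.773) * 1000 # ~ 0.146 mm
#' @export
mean_pore_diameter_4v_a <- function(v_total, a_total) {
  if (a_total <= 0) stop("a_total must be positive", call. = FALSE)
  if (v_total < 0) stop("v_total must be non-negative", call. = FALSE)
  4 * (v_total * 1e-6) / a_total  # ml -> m^3
}

#' Pore-size distribution from an intrusion curve
#'
#' Maps pressures to diameters by the Washburn relation, differences the
#' cumulative volume, and forms the log-differential distribution
#' `dV/dlogD` by central differences on the log-diameter axis.
#'
#' @param curve An [intrusion_curve] (>= 3 points).
#' @param params A [mercury_params].
#' @return A data.frame with `diameter_m` (decreasing in pressure order is
#'   reversed to increasing diameter), `dv_dlogd` (ml/g per log10 unit) and
#'   `cumulative_volume`.
#' @export
pore_size_distribution <- function(curve, params = mercury_params()) {
  stopifnot(inherits(curve, "intrusion_curve"))
  if (length(curve$pressures) < 3L) {
    stop("need at least 3 points", call. = FALSE)
  }
  d <- washburn_diameter(curve$pressures * 1e6, params)
  v <- curve$cumulative_volume
  logd <- log10(d)
  n <- length(d)
  # dV/dlogD by central differences (V grows as D shrinks, so negate)
  dvdl <- numeric(n)
  dvdl[1] <- (v[2] - v[1]) / (logd[2] - logd[1])
  dvdl[n] <- (v[n] - v[n - 1]) / (logd[n] - logd[n - 1])
  dvdl[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (logd[3:n] - logd[1:(n - 2)])
  out <- data.frame(diameter_m = d, dv_dlogd = -dvdl, cumulative_volume = v)
  out[order(out$diameter_m), , drop = FALSE]
}

#' Median pore diameter of a distribution
#'
#' Diameter at which half of the total intruded volume has entered,
#' interpolated on the log-diameter axis.
#'
#' @param curve An [intrusion_curve].
#' @param params A [mercury_params].
#' @return Median pore diameter in m.
#' @export
median_pore_diameter <- function(curve, params = mercury_params()) {
  stopifnot(inherits(curve, "intrusion_curve"))
  d <- washburn_diameter(curve$pressures * 1e6, params)
  v <- curve$cumulative_volume
  target <- max(v) / 2
  # v is non-decreasing with pressure, i.e. with shrinking d
  i <- which(v >= target)[1]
  if (i == 1L) return(d[1])
  frac <- (target - v[i - 1]) / (v[i] - v[i - 1])
  exp(log(d[i - 1]) + frac * (log(d[i]) - log(d[i - 1])))
}

#' Interstitial porosity above a diameter cutoff
#'
#' Fraction of the bulk volume in pores larger than an explicit
#' interparticle/intraparticle cutoff diameter. The cutoff is a user
#' choice; no default is supplied.
#'
#' @param curve An [intrusion_curve].
#' @param cutoff_diameter Cutoff in m separating interparticle from
#'   intraparticle pores.
#' @param params A [mercury_params].
#' @return Interstitial porosity in percent.
#' @export
interstitial_porosity <- function(curve, cutoff_diameter,
                                  params = mercury_params()) {
  stopifnot(inherits(curve, "intrusion_curve"))
  if (missing(cutoff_diameter)) {
    stop("cutoff_diameter must be supplied explicitly", call. = FALSE)
  }
  d <- washburn_diameter(curve$pressures * 1e6, params)
  v <- curve$cumulative_volume
  v_cut <- stats::approx(log(rev(d)), rev(v), xout = log(cutoff_diameter),
                         rule = 2)$y
  100 * v_cut * (curve$sample_bulk_density / 1000)
}

#' Porosimetry summary
#'
#' @param curve An [intrusion_curve].
#' @param a_total Total pore area in m^2/g (needed for the 4V/A diameter);
#'   `NA` omits it.
#' @param params A [mercury_params].
#' @return List with `porosity_pct`, `total_volume_ml_g`,
#'   `total_area_m2_g`, `mean_pore_diameter_m`, `median_pore_diameter_m`.
#' @export
porosimetry_summary <- function(curve, a_total = NA_real_,
                                params = mercury_params()) {
  stopifnot(inherits(curve, "intrusion_curve"))
  v_total <- max(curve$cumulative_volume)
  list(
    porosity_pct = porosity(curve),
    total_volume_ml_g = v_total,
    total_area_m2_g = a_total,
    mean_pore_diameter_m = if (is.na(a_total)) NA_real_ else
      mean_pore_diameter_4v_a(v_total, a_total),
    median_pore_diameter_m = median_pore_diameter(curve, params)
  )
}
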