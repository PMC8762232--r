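# Lighthill hydroacoustic source model: stress tensor from a flow field,
# compact quadrupole radiation to a virtual microphone, and A-weighted
# dB SPL spectra.

#' Acoustic propagation medium
#'
#' @param air_density Air density in kg/m^3, default 1.139.
#' @param sound_speed Speed of sound in m/s, default 340.
#' @param reference_pressure dB SPL reference in Pa, default 20e-6.
#' @return An object of class `acoustic_medium`.
#' @export
acoustic_medium <- function(air_density = 1.139, sound_speed = 340,
                            reference_pressure = 20e-6) {
  if (air_density <= 0 || sound_speed <= 0 || reference_pressure <= 0) {
    stop("medium properties must be positive", call. = FALSE)
  }
  structure(list(air_density = air_density, sound_speed = sound_speed,
                 reference_pressure = reference_pressure),
            class = "acoustic_medium")
}

# symmetric tensor components are stored in the order xx, yy, zz, xy, xz, yz
TENSOR_COMPONENTS <- c("xx", "yy", "zz", "xy", "xz", "yz")

#' Lighthill stress tensor of a flow-field snapshot
#'
#' `T_ij = rho u_i u_j + p' delta_ij (+ tau_ij)` evaluated per grid cell of
#' an axisymmetric tube flow field at one stored time. The flow is
#' incompressible, so the density-fluctuation term vanishes and the
#' pressure enters as its fluctuation about the spatial mean. The axial
#' direction is z; the velocity has no radial or swirl component in this
#' geometry.
#'
#' @param field A `flow_field`.
#' @param medium An [acoustic_medium] (kept for interface symmetry; the
#'   tensor itself uses the flow density).
#' @param t_index Index into the stored times, default 1.
#' @param pressure Optional per-cell pressure fluctuation (Pa), a matrix
#'   `nr x nz`; default zero (fully developed tube flow has no axial
#'   pressure fluctuation at fixed time beyond the linear drive, which has
#'   zero spatial mean contribution to the quadrupole).
#' @param viscous Viscous-stress flag, retained for interface
#'   compatibility: the pointwise shear `tau_rz = mu du/dr` exists, but its
#'   Cartesian components average to zero over each azimuthal ring
#'   (`tau_xz = tau_rz cos(theta)`), so the ring-cell representation
#'   carries no net viscous contribution either way.
#' @return An object of class `lighthill_source_field`: list with `T`
#'   (ncell x 6 matrix, components xx, yy, zz, xy, xz, yz in Pa),
#'   `volumes` (m^3), `positions` (ncell x 3, Cartesian, tube axis along
#'   z), `time`.
#' @export
lighthill_tensor <- function(field, medium = acoustic_medium(),
                             t_index = 1L, pressure = NULL, viscous = TRUE) {
  stopifnot(inherits(field, "flow_field"))
  r <- field$r; z <- field$z
  nr <- length(r); nz <- length(z)
  u <- field$u[, t_index]
  rho <- field$config$blood_density

  if (is.null(pressure)) {
    pfluc <- matrix(0, nr, nz)
  } else {
    if (!all(dim(pressure) == c(nr, nz))) {
      stop("pressure grid does not match the velocity grid", call. = FALSE)
    }
    pfluc <- pressure - mean(pressure)
  }

  # ring volumes: annular cells of the axisymmetric grid revolved about z
  dr <- r[2] - r[1]
  dz <- z[2] - z[1]
  r_lo <- pmax(r - dr / 2, 0)
  r_hi <- pmin(r + dr / 2, max(r))
  ring_area <- pi * (r_hi^2 - r_lo^2)
  vol_r <- ring_area * dz

  ncell <- nr * nz
  T <- matrix(0, ncell, 6, dimnames = list(NULL, TENSOR_COMPONENTS))
  volumes <- numeric(ncell)
  positions <- matrix(0, ncell, 3, dimnames = list(NULL, c("x", "y", "z")))
  # represent each ring by its on-x-axis point; the compact integral only
  # needs volumes and component sums, which are exact for the axisymmetric
  # Cartesian average (mean of u_x u_y terms over a ring vanishes)
  for (j in seq_len(nz)) {
    rows <- ((j - 1L) * nr + 1L):(j * nr)
    T[rows, "zz"] <- rho * u^2 + pfluc[, j]
    T[rows, "xx"] <- pfluc[, j]
    T[rows, "yy"] <- pfluc[, j]
    volumes[rows] <- vol_r
    positions[rows, 1] <- r
    positions[rows, 3] <- z[j]
  }
  structure(
    list(T = T, volumes = volumes, positions = positions,
         time = field$time[t_index]),
    class = "lighthill_source_field"
  )
}

#' @export
print.lighthill_source_field <- function(x, ...) {
  cat(sprintf("<lighthill_source_field> %d cells at t = %.4g s, max |T| = %.3g Pa\n",
              nrow(x$T), x$time, max(abs(x$T))))
  invisible(x)
}

#' Volume-integrated Lighthill quadrupole time series
#'
#' Integrates the Lighthill tensor over the source volume at every stored
#' time of a flow field: `Q_ij(t) = sum_cells T_ij V_cell`. This is the
#' quantity the compact (acoustically small source) radiation formula
#' needs.
#'
#' @param field A `flow_field`.
#' @param medium An [acoustic_medium].
#' @param viscous Passed to [lighthill_tensor()].
#' @return An object of class `lighthill_sources`: list with `time`, `Q`
#'   (nt x 6 matrix, Pa m^3), `centroid` (m), `extent` (max source radius
#'   about the centroid, m).
#' @export
lighthill_series <- function(field, medium = acoustic_medium(),
                             viscous = TRUE) {
  stopifnot(inherits(field, "flow_field"))
  nt <- length(field$time)
  Q <- matrix(0, nt, 6, dimnames = list(NULL, TENSOR_COMPONENTS))
  for (k in seq_len(nt)) {
    sf <- lighthill_tensor(field, medium, t_index = k, viscous = viscous)
    Q[k, ] <- colSums(sf$T * sf$volumes)
  }
  sf1 <- lighthill_tensor(field, medium, t_index = 1L, viscous = viscous)
  centroid <- colSums(sf1$positions * sf1$volumes) / sum(sf1$volumes)
  extent <- max(sqrt(rowSums(sweep(sf1$positions, 2, centroid)^2)))
  lighthill_sources(field$time, Q, centroid, extent)
}

#' Construct an integrated quadrupole source series directly
#'
#' @param time Uniformly sampled times in s.
#' @param Q nt x 6 matrix of integrated tensor components
#'   (xx, yy, zz, xy, xz, yz) in Pa m^3.
#' @param centroid Source centroid (length-3, m).
#' @param extent Source region radius about the centroid in m.
#' @return An object of class `lighthill_sources`.
#' @export
lighthill_sources <- function(time, Q, centroid = c(0, 0, 0), extent = 0) {
  Q <- as.matrix(Q)
  if (ncol(Q) != 6L) stop("Q must have 6 columns", call. = FALSE)
  if (nrow(Q) != length(time)) {
    stop("Q rows must match time length", call. = FALSE)
  }
  colnames(Q) <- TENSOR_COMPONENTS
  structure(list(time = time, Q = Q, centroid = centroid, extent = extent),
            class = "lighthill_sources")
}

#' Radiate a quadrupole source series to a virtual microphone
#'
#' Compact-source far-field solution of the Lighthill wave equation: with
#' the double time derivative moved outside the volume integral,
#' `p'(x, t) = x_i x_j / (4 pi c0^2 |x|^3) * d2/dt2 Q_ij(t - |x| / c0)`,
#' where `x` is measured from the source centroid. The second derivative
#' is taken by central differences at the stored sampling step and the
#' retarded time is interpolated linearly.
#'
#' @param sources A `lighthill_sources` series (or a `flow_field`, which is
#'   integrated via [lighthill_series()] first).
#' @param observer Microphone position (length-3, m), outside the source
#'   region.
#' @param medium An [acoustic_medium].
#' @return An object of class `microphone_result`: list with `position`,
#'   `time`, `pressure` (Pa), `rate` (Hz).
#' @export
radiate <- function(sources, observer, medium = acoustic_medium()) {
  if (inherits(sources, "flow_field")) {
    sources <- lighthill_series(sources, medium)
  }
  stopifnot(inherits(sources, "lighthill_sources"))
  x <- as.numeric(observer) - sources$centroid
  rdist <- sqrt(sum(x^2))
  if (rdist <= sources$extent) {
    stop("observer lies inside the source region; the compact far-field approximation does not apply",
         call. = FALSE)
  }
  dt <- sources$time[2] - sources$time[1]
  nt <- length(sources$time)
  # second time derivative of each component by central differences
  d2Q <- apply(sources$Q, 2L, function(q) {
    d <- numeric(nt)
    d[2:(nt - 1)] <- (q[3:nt] - 2 * q[2:(nt - 1)] + q[1:(nt - 2)]) / dt^2
    d[1] <- d[2]; d[nt] <- d[nt - 1]
    d
  })
  # contract x_i x_j over the symmetric tensor (off-diagonals twice)
  xi <- x
  w6 <- c(xi[1]^2, xi[2]^2, xi[3]^2,
          2 * xi[1] * xi[2], 2 * xi[1] * xi[3], 2 * xi[2] * xi[3])
  amp <- as.numeric(d2Q %*% w6) / (4 * pi * medium$sound_speed^2 * rdist^3)
  # retarded-time shift: p(t) uses the source at t - r/c0
  delay <- rdist / medium$sound_speed
  t_out <- sources$time
  p <- stats::approx(sources$time + delay, amp, xout = t_out,
                     rule = 2)$y
  structure(
    list(position = as.numeric(observer), time = t_out, pressure = p,
         rate = 1 / dt, reference_pressure = medium$reference_pressure),
    class = "microphone_result"
  )
}

#' @export
print.microphone_result <- function(x, ...) {
  cat(sprintf("<microphone_result> %d samples @ %.4g Hz, peak |p| = %.3g Pa\n",
              length(x$pressure), x$rate, max(abs(x$pressure))))
  invisible(x)
}

#' A-weighting curve
#'
#' Standard IEC A-weighting: the rational magnitude response with poles at
#' 20.6, 107.7, 737.9 and 12194 Hz, normalised to 0 dB at 1 kHz.
#'
#' @param f Frequencies in Hz (> 0).
#' @return Weight in dB to add to an unweighted dB SPL spectrum.
#' @examples
#' a_weighting_db(1000) # ~ 0
#' a_weighting_db(100)  # ~ -19.1
#' @export
a_weighting_db <- function(f) {
  if (any(f <= 0)) stop("frequencies must be positive", call. = FALSE)
  ra <- (12194^2 * f^4) /
    ((f^2 + 20.6^2) * sqrt((f^2 + 107.7^2) * (f^2 + 737.9^2)) *
       (f^2 + 12194^2))
  20 * log10(ra) + 2.00
}

#' Spectrum of a microphone result
#'
#' One-sided amplitude spectrum of the pressure trace in dB SPL, with an
#' optional A-weighted companion.
#'
#' @param result A `microphone_result`.
#' @param floor_db Clamp in dB, default -120.
#' @return List with `frequencies` (Hz), `db_spl`, `db_a`.
#' @export
microphone_spectrum <- function(result, floor_db = -120) {
  stopifnot(inherits(result, "microphone_result"))
  p <- result$pressure
  n <- length(p)
  nf <- n %/% 2 + 1L
  amp <- Mod(stats::fft(p))[seq_len(nf)] / n
  if (nf > 2L) amp[2:(nf - 1L)] <- 2 * amp[2:(nf - 1L)]
  freq <- (seq_len(nf) - 1L) * result$rate / n
  db <- 20 * log10(pmax(amp / result$reference_pressure,
                        10^(floor_db / 20)))
  dba <- db
  dba[-1] <- db[-1] + a_weighting_db(freq[-1])
  list(frequencies = freq, db_spl = db, db_a = dba)
}

#' Peak of a level spectrum
#'
#' Maximum of a dB spectrum and its frequency; ties (within `tie_tol` dB)
#' are broken toward the lower frequency.
#'
#' @param db Levels in dB.
#' @param frequencies Frequencies in Hz, same length.
#' @param tie_tol Levels within this of the maximum count as tied, default
#'   1e-9 dB.
#' @return List with `db` and `frequency`.
#' @examples
#' peak_amplitude(c(70.4, 50), c(42, 400)) # 70.4 dB at 42 Hz
#' @export
peak_amplitude <- function(db, frequencies, tie_tol = 1e-9) {
  if (length(db) == 0L) stop("empty spectrum", call. = FALSE)
  if (length(db) != length(frequencies)) {
    stop("db and frequencies differ in length", call. = FALSE)
  }
  mx <- max(db)
  cand <- which(db >= mx - tie_tol)
  i <- cand[which.min(frequencies[cand])]
  list(db = db[i], frequency = frequencies[i])
}
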