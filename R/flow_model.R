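# Pulsatile laminar flow in a straight rigid circular tube: the classical
# Womersley analytic solution and a finite-difference axisymmetric solver
# that cross-validate each other. The tube is a reduced surrogate for the
# transverse-sigmoid sinus; downstream acoustic modules need only a
# plausible space-time velocity field.

#' Flow configuration
#'
#' Fluid properties, tube geometry, and time stepping for the pulsatile
#' flow surrogate. Defaults are venous blood (density 1050 kg/m^3, dynamic
#' viscosity 0.00345 Pa s), a 3.5 mm tube radius typical of the sigmoid
#' sinus calibre, a 1.46 s cardiac period, a 5e-5 s time step and two
#' computed cycles with the second cycle taken as representative.
#'
#' @param blood_density Fluid density in kg/m^3.
#' @param viscosity Dynamic viscosity in Pa s.
#' @param tube_radius Tube radius in m.
#' @param tube_length Tube length in m.
#' @param dt Time step in s.
#' @param cycles Number of cardiac cycles to integrate (>= 2; the second
#'   is the representative one).
#' @param period Cardiac period in s.
#' @param nr,nz Radial and axial node counts (default 41 x 101).
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(blood_density = 1050, viscosity = 0.00345,
                        tube_radius = 0.0035, tube_length = 0.05,
                        dt = 5e-5, cycles = 2L, period = 1.46,
                        nr = 41L, nz = 101L) {
  vals <- c(blood_density, viscosity, tube_radius, tube_length, dt, period)
  if (any(vals <= 0)) stop("flow parameters must be positive", call. = FALSE)
  if (cycles < 2L) stop("cycles must be >= 2", call. = FALSE)
  structure(
    list(blood_density = blood_density, viscosity = viscosity,
         tube_radius = tube_radius, tube_length = tube_length, dt = dt,
         cycles = as.integer(cycles), period = period,
         nr = as.integer(nr), nz = as.integer(nz)),
    class = "flow_config"
  )
}

#' Reynolds number of the tube flow
#'
#' `Re = rho v D / mu` with `D = 2 R`.
#'
#' @param config A [flow_config].
#' @param mean_velocity Cycle-mean velocity in m/s.
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds(flow_config(), 0.5) # ~ 1065 for a 7 mm vessel
#' @export
reynolds <- function(config, mean_velocity) {
  stopifnot(inherits(config, "flow_config"))
  config$blood_density * mean_velocity * 2 * config$tube_radius /
    config$viscosity
}

#' Womersley number
#'
#' `alpha = R sqrt(omega rho / mu)` at the fundamental angular frequency
#' `omega = 2 pi / period`.
#'
#' @param config A [flow_config].
#' @param harmonic Harmonic index (1 = fundamental).
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(config, harmonic = 1) {
  stopifnot(inherits(config, "flow_config"))
  omega <- 2 * pi * harmonic / config$period
  config$tube_radius * sqrt(omega * config$blood_density / config$viscosity)
}

# Bessel J0 for complex argument by power series; accurate to ~1e-12 for
# |z| <~ 20, ample for Womersley numbers up to ~15.
besselJ0_complex <- function(z) {
  out <- z
  for (m in seq_along(z)) {
    zz <- -0.25 * z[m]^2
    term <- 1 + 0i
    s <- term
    for (k in 1:200) {
      term <- term * zz / (k * k)
      s <- s + term
      if (Mod(term) < 1e-17 * max(Mod(s), 1)) break
    }
    out[m] <- s
  }
  out
}

flow_field_new <- function(r, z, u, time, gradient, config) {
  structure(list(r = r, z = z, u = u, time = time, gradient = gradient,
                 config = config),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %d radial x %d axial nodes, %d stored times (%.3g-%.3g s)\n",
    length(x$r), length(x$z), length(x$time), min(x$time), max(x$time)))
  cat(sprintf("  peak axial velocity %.4g m/s\n", max(abs(x$u))))
  invisible(x)
}

# area-weighted cross-section mean of a radial profile (trapezoid in r*dr)
section_mean <- function(r, u) {
  w <- r
  tw <- (w[-1] + w[-length(w)]) / 2 * diff(r)
  um <- (u[-1] + u[-length(u)]) / 2
  sum(tw * um) / sum(tw)
}

#' Cross-section mean velocity series of a flow field
#'
#' @param field A `flow_field`.
#' @return Numeric vector, one mean velocity per stored time.
#' @export
mean_velocity_series <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  apply(field$u, 2L, function(col) section_mean(field$r, col))
}

#' Womersley analytic solution for pulsatile tube flow
#'
#' Superposes the steady Poiseuille component and the classical Womersley
#' profile for each oscillatory harmonic of the driving pressure gradient:
#' for harmonic `n` at `omega_n = 2 pi n / period` with complex amplitude
#' `G_n` (the gradient is `Re(sum_n G_n exp(i omega_n t))`, positive G
#' driving flow in +z),
#' `u_n(r, t) = Re[ (G_n / (i rho omega_n))
#'              (1 - J0(i^{3/2} alpha_n r / R) / J0(i^{3/2} alpha_n))
#'              exp(i omega_n t) ]`.
#'
#' @param config A [flow_config].
#' @param pressure_gradient_harmonics Complex vector of gradient amplitudes
#'   in Pa/m; element 1 is the steady component (n = 0), element k the
#'   harmonic n = k - 1.
#' @param n_times Number of stored time points over one period, default
#'   200.
#' @return A `flow_field` over one representative period.
#' @export
womersley_solution <- function(config, pressure_gradient_harmonics,
                               n_times = 200L) {
  stopifnot(inherits(config, "flow_config"))
  g <- as.complex(pressure_gradient_harmonics)
  R <- config$tube_radius
  r <- seq(0, R, length.out = config$nr)
  z <- seq(0, config$tube_length, length.out = config$nz)
  time <- seq(0, config$period, length.out = n_times + 1L)[-(n_times + 1L)]
  u <- matrix(0, nrow = length(r), ncol = length(time))
  grad <- rep(Re(g[1]), length(time))
  # steady Poiseuille component
  u <- u + outer(Re(g[1]) / (4 * config$viscosity) * (R^2 - r^2),
                 rep(1, length(time)))
  if (length(g) > 1L) {
    for (k in 2:length(g)) {
      n <- k - 1L
      if (Mod(g[k]) == 0) next
      omega <- 2 * pi * n / config$period
      alpha <- R * sqrt(omega * config$blood_density / config$viscosity)
      i32 <- complex(modulus = 1, argument = 3 * pi / 4)  # i^{3/2}
      denom <- besselJ0_complex(i32 * alpha)
      shape <- 1 - besselJ0_complex(i32 * alpha * r / R) / denom
      phasor <- exp(1i * omega * time)
      u <- u + Re(outer(g[k] / (1i * config$blood_density * omega) * shape,
                        phasor))
      grad <- grad + Re(g[k] * phasor)
    }
  }
  u[length(r), ] <- 0  # enforce no-slip exactly against rounding
  flow_field_new(r, z, u, time, grad, config)
}

#' Finite-difference solution of transient laminar tube flow
#'
#' Integrates the axisymmetric momentum equation
#' `rho du/dt = G(t) + mu (d2u/dr2 + (1/r) du/dr)` for fully developed flow
#' in a straight rigid tube (the convective term vanishes identically in
#' this geometry), with an explicit scheme and a per-step uniform
#' pressure-gradient correction that enforces the prescribed inlet
#' cross-section mean-velocity waveform. Integration covers
#' `config$cycles` cardiac cycles; the last cycle is returned as the
#' representative one, along with the relative L2 difference between the
#' last two cycles as a periodicity check.
#'
#' @param config A [flow_config].
#' @param inlet A [signal_trace] of cross-section mean velocity in m/s,
#'   covering (at least) one period, treated as periodic; or a single
#'   number for a constant inlet.
#' @param store_every Store every k-th step; default chosen to keep about
#'   400 frames per cycle.
#' @return A `flow_field` over the representative (last) cycle, with extra
#'   elements `periodicity` (relative cycle-to-cycle L2 difference) and
#'   `gradient` (driving pressure gradient at the stored times, Pa/m).
#' @export
solve_transient_laminar <- function(config, inlet, store_every = NULL) {
  stopifnot(inherits(config, "flow_config"))
  R <- config$tube_radius
  nr <- config$nr
  r <- seq(0, R, length.out = nr)
  dr <- r[2] - r[1]
  nu <- config$viscosity / config$blood_density
  lam <- nu * config$dt / dr^2
  if (lam > 0.25) {
    stop(sprintf(
      "time step violates diffusive stability (nu*dt/dr^2 = %.3f > 0.25); try dt <= %.2e s",
      lam, 0.25 * dr^2 / nu), call. = FALSE)
  }
  steps_per_cycle <- round(config$period / config$dt)
  n_steps <- steps_per_cycle * config$cycles
  if (is.null(store_every)) store_every <- max(1L, steps_per_cycle %/% 400L)

  # target mean-velocity waveform sampled on the step grid of one cycle
  tt <- (seq_len(steps_per_cycle) - 1L) * config$dt
  target <- if (inherits(inlet, "signal_trace")) {
    ti <- trace_times(inlet) - inlet$t0
    stats::approx(ti, inlet$samples,
                  xout = tt %% max(ti[length(ti)], config$period),
                  rule = 2)$y
  } else rep(as.numeric(inlet), steps_per_cycle)

  # a uniform bump on the interior nodes moves the area mean by bump * gain
  mean_of <- function(u) section_mean(r, u)
  gain <- { uu <- rep(0, nr); uu[-nr] <- 1; mean_of(uu) }

  # start from the analytic periodic profile implied by the inlet waveform
  # (Womersley shape per Fourier harmonic of the target mean velocity)
  # instead of from rest, so the start-up transient is already small
  vhat <- stats::fft(target) / steps_per_cycle
  u <- 2 * Re(vhat[1]) * (1 - (r / R)^2)
  n_harm <- min(40L, steps_per_cycle %/% 2L - 1L)
  i32 <- complex(modulus = 1, argument = 3 * pi / 4)
  for (h in seq_len(n_harm)) {
    if (Mod(vhat[h + 1L]) < 1e-12 * max(Mod(vhat[1]), 1e-12)) next
    omega <- 2 * pi * h / config$period
    alpha <- R * sqrt(omega / nu)
    shape <- 1 - besselJ0_complex(i32 * alpha * r / R) /
      besselJ0_complex(i32 * alpha)
    shape_mean <- section_mean(r, shape)
    # one-sided harmonic: double the positive-frequency coefficient
    u <- u + Re(2 * vhat[h + 1L] * shape / shape_mean)
  }
  u[nr] <- 0
  idx_i <- 2:(nr - 1L)
  inv_dr2 <- 1 / dr^2
  inv_2rdr <- 1 / (2 * r[idx_i] * dr)
  store_idx <- seq(store_every, steps_per_cycle, by = store_every)
  n_store <- length(store_idx)
  u_last <- matrix(0, nr, n_store)
  u_prev <- matrix(0, nr, n_store)
  g_store <- numeric(n_store)
  t_store <- numeric(n_store)
  diverged <- FALSE

  for (s in seq_len(n_steps)) {
    lap <- numeric(nr)
    lap[1] <- 4 * (u[2] - u[1]) * inv_dr2
    lap[idx_i] <- (u[idx_i + 1L] - 2 * u[idx_i] + u[idx_i - 1L]) * inv_dr2 +
      (u[idx_i + 1L] - u[idx_i - 1L]) * inv_2rdr
    ustar <- u + config$dt * nu * lap
    ustar[nr] <- 0
    cyc_pos <- ((s - 1L) %% steps_per_cycle) + 1L
    deficit <- target[cyc_pos] - mean_of(ustar)
    bump <- deficit / gain
    u <- ustar
    u[-nr] <- u[-nr] + bump
    if (!all(is.finite(u)) || max(abs(u)) > 1e4) { diverged <- TRUE; break }
    k <- match(cyc_pos, store_idx)
    if (!is.na(k)) {
      cyc <- (s - 1L) %/% steps_per_cycle + 1L
      if (cyc == config$cycles) {
        u_last[, k] <- u
        g_store[k] <- config$blood_density * bump / config$dt
        t_store[k] <- (s - 1L) * config$dt
      } else if (cyc == config$cycles - 1L) {
        u_prev[, k] <- u
      }
    }
  }
  if (diverged) stop("transient solver diverged", call. = FALSE)

  periodicity <- sqrt(sum((u_last - u_prev)^2)) /
    max(sqrt(sum(u_last^2)), .Machine$double.eps)
  z <- seq(0, config$tube_length, length.out = config$nz)
  out <- flow_field_new(r, z, u_last, t_store - min(t_store), g_store, config)
  out$periodicity <- periodicity
  out
}
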