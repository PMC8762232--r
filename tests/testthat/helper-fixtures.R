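# shared fixtures and small oracles for the suite

tone_trace <- function(freq, duration = 2, rate = 1000, amp = 1, phase = 0,
                       unit = "dimensionless") {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  signal_trace(amp * sin(2 * pi * freq * t + phase), rate = rate, unit = unit)
}

rel_l2 <- function(x, ref) sqrt(sum((x - ref)^2) / sum(ref^2))

# exhaustive-enumeration rank-sum oracle, written independently of
# compare_segments: enumerates group-a index sets via binary masks
ranksum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  masks <- masks[rowSums(masks) == na, , drop = FALSE]
  us <- apply(masks, 1L, function(m) sum(r[as.logical(m)]) - na * (na + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# analytic Womersley profile for one steady + one fundamental harmonic,
# evaluated on given radii/times; independent of the package solver
womersley_oracle <- function(cfg, g_steady, g_osc, r, times) {
  R <- cfg$tube_radius
  om <- 2 * pi / cfg$period
  i32 <- complex(modulus = 1, argument = 3 * pi / 4)
  alpha <- R * sqrt(om * cfg$blood_density / cfg$viscosity)
  # complex J0 by direct series summation (independent implementation)
  j0 <- function(z) {
    vapply(z, function(zz) {
      term <- 1 + 0i; s <- term
      for (k in 1:60) {
        term <- term * (-(zz / 2)^2) / k^2
        s <- s + term
      }
      s
    }, complex(1))
  }
  shape <- 1 - j0(i32 * alpha * r / R) / j0(i32 * alpha)
  out <- sapply(times, function(tk) {
    g_steady / (4 * cfg$viscosity) * (R^2 - r^2) +
      Re(g_osc / (1i * cfg$blood_density * om) * shape * exp(1i * om * tk))
  })
  out[length(r), ] <- 0
  out
}
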