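test_that("lighthill tensor vanishes for quiescent flow and scales as u^2", {
  cfg <- flow_config()
  ffz <- solve_transient_laminar(cfg, 0)
  sf <- lighthill_tensor(ffz)
  expect_equal(max(abs(sf$T)), 0)
  # scaling: doubling the velocity field quadruples the rho u_i u_j term
  ff <- solve_transient_laminar(cfg, 0.2)
  s1 <- lighthill_tensor(ff, t_index = 10L)
  ff2 <- ff; ff2$u <- 2 * ff$u
  s2 <- lighthill_tensor(ff2, t_index = 10L)
  expect_equal(s2$T[, "zz"], 4 * s1$T[, "zz"], tolerance = 1e-12)
  # symmetric storage: only the six independent components are carried,
  # and the momentum-flux part lives on the axial diagonal for axial flow
  expect_equal(max(abs(s1$T[, c("xy", "xz", "yz")])), 0)
  # pressure grid mismatch is a configuration error
  expect_error(lighthill_tensor(ff, pressure = matrix(0, 2, 2)),
               "does not match")
})

test_that("time-constant sources radiate nothing", {
  cfg <- flow_config()
  ff <- solve_transient_laminar(cfg, 0.2)  # steady: Q constant in time
  mr <- radiate(ff, observer = c(0.1, 0, 0.025))
  expect_lt(max(abs(mr$pressure)), 1e-12)
})

test_that("radiated pressure is linear in T and decays as 1/r", {
  f0 <- 40
  tt <- seq(0, 0.5, by = 5e-5)
  Q <- matrix(0, length(tt), 6)
  Q[, 1] <- 1e-6 * sin(2 * pi * f0 * tt)
  src <- lighthill_sources(tt, Q, centroid = c(0, 0, 0), extent = 0.005)
  # closed-form far-field amplitude on the x-axis:
  # p = (d2Q_xx/dt2) / (4 pi c0^2 r)
  core <- 200:9800
  r_ref <- 0.1
  p_ref <- radiate(src, c(r_ref, 0, 0))
  amp_analytic <- (2 * pi * f0)^2 * 1e-6 / (4 * pi * 340^2 * r_ref)
  expect_equal(max(abs(p_ref$pressure[core])), amp_analytic,
               tolerance = 0.005)
  # 1/r decay within 2% over a decade of distances
  for (rr in c(0.2, 0.5, 1.0)) {
    p <- radiate(src, c(rr, 0, 0))
    ratio <- max(abs(p_ref$pressure[core])) / max(abs(p$pressure[core]))
    expect_equal(ratio, rr / r_ref, tolerance = 0.02)
  }
  # exact linearity
  src2 <- lighthill_sources(tt, 2 * Q, centroid = c(0, 0, 0),
                            extent = 0.005)
  p2 <- radiate(src2, c(r_ref, 0, 0))
  expect_identical(p2$pressure, 2 * p_ref$pressure)
  # all-zero sources radiate nothing
  z <- radiate(lighthill_sources(tt, matrix(0, length(tt), 6)),
               c(0.1, 0, 0))
  expect_equal(max(abs(z$pressure)), 0)
})

test_that("near-field observers are refused", {
  tt <- seq(0, 0.1, by = 1e-4)
  src <- lighthill_sources(tt, matrix(1, length(tt), 6),
                           centroid = c(0, 0, 0), extent = 0.02)
  expect_error(radiate(src, c(0.01, 0, 0)), "inside the source region")
})

test_that("a-weighting matches the standard curve", {
  expect_equal(a_weighting_db(1000), 0, tolerance = 0.1)
  expect_equal(a_weighting_db(100), -19.1, tolerance = 0.2)
  # monotone increasing from 20 Hz to 1 kHz
  f <- exp(seq(log(20), log(1000), length.out = 40))
  expect_true(all(diff(a_weighting_db(f)) > 0))
  expect_error(a_weighting_db(0), "positive")
})

test_that("microphone spectra agree with A-weighting at 1 kHz", {
  tr <- tone_trace(1000, duration = 0.5, rate = 8000, amp = 0.02)
  mr <- structure(list(position = c(1, 0, 0), time = trace_times(tr),
                       pressure = tr$samples, rate = tr$rate,
                       reference_pressure = 20e-6),
                  class = "microphone_result")
  sp <- microphone_spectrum(mr)
  i <- which.min(abs(sp$frequencies - 1000))
  expect_equal(sp$db_spl[i], sp$db_a[i], tolerance = 0.1)
  pk <- peak_amplitude(sp$db_a[-1], sp$frequencies[-1])
  expect_equal(pk$frequency, 1000, tolerance = 5)
})

test_that("peak extraction breaks ties toward the lower frequency", {
  expect_equal(peak_amplitude(c(50, 70.4), c(400, 42))$frequency, 42)
  expect_equal(peak_amplitude(c(50, 70.4), c(400, 42))$db, 70.4)
  expect_equal(peak_amplitude(c(60, 60), c(40, 400))$frequency, 40)
  expect_equal(peak_amplitude(rep(55, 5), c(100, 50, 20, 300, 70))$frequency,
               20)
  expect_error(peak_amplitude(numeric(0), numeric(0)), "empty")
})
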