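test_that("washburn inversion matches the printed detection limits", {
  # 400 MPa ceiling -> ~3.1 nm floor
  expect_equal(washburn_diameter(400e6), 3.1e-9, tolerance = 0.01)
  # 950 um ceiling -> ~1.31 kPa
  expect_equal(washburn_pressure(950e-6), 1.31e3, tolerance = 0.01)
  # inverse proportionality and the constant product invariant
  P <- 10^seq(4, 8.6, length.out = 20)
  d <- washburn_diameter(P)
  expect_equal(washburn_diameter(P / 2), 2 * d, tolerance = 1e-12)
  expect_equal(d * P, rep(d[1] * P[1], 20), tolerance = 1e-12)
  expect_error(mercury_params(contact_angle = 80), "90")
  expect_error(washburn_diameter(-5), "positive")
})

test_that("porosity is intruded volume times bulk density in percent", {
  expect_equal(round(porosity(28.28, 34.2), 1), 96.7)
  expect_equal(porosity(0.0376, 945.3), 3.55, tolerance = 0.01)
  expect_equal(porosity(0, 945.3), 0)
  expect_error(porosity(50, 945.3), "inconsistent")
})

test_that("4V/A mean pore diameter matches the instrument convention", {
  expect_equal(mean_pore_diameter_4v_a(28.28, 0.773) * 1000, 0.146,
               tolerance = 0.005)
  expect_equal(mean_pore_diameter_4v_a(0.0376, 0.190) * 1e9, 791.6,
               tolerance = 0.001)
  expect_equal(mean_pore_diameter_4v_a(0, 0.5), 0)
  expect_error(mean_pore_diameter_4v_a(1, 0), "positive")
})

test_that("pore-size distribution round-trips a log-normal generator", {
  curve <- gen_intrusion_curve(list(median_um = 0.1, sdlog = 0.6,
                                    weights = 1),
                               porosity = 0.7, bulk_density = 300)
  expect_equal(median_pore_diameter(curve) * 1e6, 0.1, tolerance = 0.1)
  dist <- pore_size_distribution(curve)
  # distribution mode near the configured median
  mode_d <- dist$diameter_m[which.max(dist$dv_dlogd)]
  expect_equal(mode_d * 1e6, 0.1, tolerance = 0.35)
  expect_true(all(dist$dv_dlogd >= -1e-9))
})

test_that("degenerate intrusion curves give delta-like or flat distributions", {
  # single step: mass concentrated at the step diameter
  p <- c(1, 2, 4, 8, 16)
  v <- c(0, 0, 1, 1, 1)
  curve <- intrusion_curve(p, v, sample_bulk_density = 500)
  dist <- pore_size_distribution(curve)
  step_d <- washburn_diameter(4e6)
  expect_equal(dist$diameter_m[which.max(dist$dv_dlogd)], step_d,
               tolerance = 0.6)
  # uniform dV per log-decade of diameter -> flat dV/dlogD
  d_target <- 10^seq(-6, -5, length.out = 30)
  p_mpa <- washburn_pressure(d_target) / 1e6
  cu <- intrusion_curve(rev(p_mpa), seq(0, 1, length.out = 30), 100)
  du <- pore_size_distribution(cu)
  inner <- du$dv_dlogd[3:28]
  expect_lt(stats::sd(inner) / mean(inner), 0.01)
})

test_that("porosity is invariant to re-sampling the pressure grid", {
  dense <- gen_intrusion_curve(list(median_um = 1, sdlog = 0.5, weights = 1),
                               porosity = 0.5, bulk_density = 400,
                               n_points = 400L)
  coarse <- gen_intrusion_curve(list(median_um = 1, sdlog = 0.5, weights = 1),
                                porosity = 0.5, bulk_density = 400,
                                n_points = 40L)
  expect_lt(abs(porosity(dense) - porosity(coarse)), 0.1)
})

test_that("non-monotone volume and interstitial cutoff are policed", {
  expect_error(intrusion_curve(c(1, 2, 3), c(0, 1, 0.5), 100), "decreases")
  curve <- gen_intrusion_curve(list(median_um = c(0.1, 50),
                                    sdlog = c(0.4, 0.4),
                                    weights = c(0.5, 0.5)),
                               porosity = 0.8, bulk_density = 200)
  expect_error(interstitial_porosity(curve), "explicitly")
  ip <- interstitial_porosity(curve, cutoff_diameter = 5e-6)
  expect_equal(ip, 40, tolerance = 0.05)  # half the volume sits above 5 um
})

test_that("intrusion CSV dialect round-trips", {
  curve <- gen_intrusion_curve(list(median_um = 10, sdlog = 0.4, weights = 1),
                               porosity = 0.3, bulk_density = 500)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_intrusion_csv(curve, path)
  back <- read_intrusion_csv(path)
  expect_equal(back$pressures, curve$pressures, tolerance = 1e-9)
  expect_equal(back$cumulative_volume, curve$cumulative_volume,
               tolerance = 1e-9)
  expect_equal(porosity(back), porosity(curve), tolerance = 1e-6)
})
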