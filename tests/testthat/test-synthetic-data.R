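test_that("generator_config validates its invariants", {
  expect_error(generator_config(heart_period = 0), "heart_period")
  expect_error(generator_config(duration = 1), "two cardiac cycles")
  expect_error(generator_config(sample_rate_audio = -1), "sample rates")
  cfg <- generator_config(seed = 5)
  expect_equal(cfg$heart_period, 1.46)
  expect_equal(cfg$sample_rate_displacement, 1000)
})

test_that("displacement traces are pulse-synchronous at the cardiac fundamental", {
  cfg <- generator_config(seed = 7, duration = 10, noise_sd = 0.002)
  tr <- gen_displacement_trace(cfg, median_amp = 0.092)
  expect_s3_class(tr, "signal_trace")
  expect_equal(tr$unit, "mm")
  f0 <- detect_fundamental(tr)
  expect_equal(f0, 1 / 1.46, tolerance = 0.02 / 0.685)
  expect_lt(abs(stats::median(abs(tr$samples)) - 0.092) / 0.092, 0.1)
})

test_that("noiseless displacement is exactly periodic across cycles", {
  cfg <- generator_config(seed = 1, duration = 2.92, heart_period = 1.46,
                          noise_sd = 0)
  tr <- gen_displacement_trace(cfg, median_amp = 0.012)
  n_cycle <- 1460
  c1 <- tr$samples[1:n_cycle]
  c2 <- tr$samples[(n_cycle + 1):(2 * n_cycle)]
  expect_equal(max(c1) - min(c1), max(c2) - min(c2), tolerance = 1e-6)
  expect_lt(max(abs(c1 - c2)), 1e-9)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- generator_config(seed = 11, duration = 4, noise_sd = 0.01)
  expect_identical(gen_displacement_trace(cfg, 0.05)$samples,
                   gen_displacement_trace(cfg, 0.05)$samples)
  expect_identical(gen_pt_audio(cfg, 60)$samples,
                   gen_pt_audio(cfg, 60)$samples)
  cfg2 <- generator_config(seed = 12, duration = 4, noise_sd = 0.01)
  expect_false(identical(gen_displacement_trace(cfg, 0.05)$samples,
                         gen_displacement_trace(cfg2, 0.05)$samples))
})

test_that("tinnitus-like audio is calibrated and band-limited", {
  cfg <- generator_config(seed = 3, duration = 5)
  au <- gen_pt_audio(cfg, peak_db_spl = 64.0, band_limit = 2000)
  expect_equal(to_db_spl(max(abs(au$samples))), 64.0, tolerance = 0.5)
  # independent periodogram: out-of-band / in-band energy ratio
  pg <- stats::spec.pgram(stats::ts(au$samples, frequency = au$rate),
                          plot = FALSE, taper = 0)
  ratio <- sum(pg$spec[pg$freq > 2000]) / sum(pg$spec[pg$freq <= 2000])
  expect_lt(ratio, 1e-4)
  # spectral peak above the band edge at least 40 dB below in-band peak
  db <- 10 * log10(pg$spec)
  expect_lt(max(db[pg$freq > 2000]), max(db[pg$freq <= 2000]) - 40)
})

test_that("audio calibration pins 0 dB SPL to 20 uPa and rejects >200 Pa", {
  cfg <- generator_config(seed = 3, duration = 3)
  au0 <- gen_pt_audio(cfg, peak_db_spl = 0)
  expect_equal(max(abs(au0$samples)), 20e-6, tolerance = 1e-9)
  expect_error(gen_pt_audio(cfg, peak_db_spl = 145), "200 Pa")
  au5 <- gen_pt_audio(cfg, peak_db_spl = 64, band_limit = 500)
  pg <- stats::spec.pgram(stats::ts(au5$samples, frequency = au5$rate),
                          plot = FALSE, taper = 0)
  expect_lt(sum(pg$spec[pg$freq > 500]) / sum(pg$spec[pg$freq <= 500]), 1e-4)
})

test_that("doppler waveform has configured mean, floor and excursion", {
  cfg <- generator_config(seed = 1, duration = 5.84)
  const <- gen_doppler_waveform(cfg, 0.5, pulsatility = 0)
  expect_equal(range(const$samples), c(0.5, 0.5))
  dw <- gen_doppler_waveform(cfg, 0.5, pulsatility = 0.5)
  expect_equal(mean(dw$samples), 0.5, tolerance = 0.02)
  expect_gte(min(dw$samples), 0.5 * (1 - 0.5) - 1e-12)
  expect_equal(max(dw$samples) / min(dw$samples), 3, tolerance = 1e-6)
  expect_equal(detect_fundamental(dw), 1 / 1.46, tolerance = 0.03)
})

test_that("doppler-consistent tube flow reproduces the clinical Reynolds number", {
  cfg <- flow_config()  # 3.5 mm radius -> 7 mm diameter
  expect_equal(reynolds(cfg, 0.5), 1050 * 0.5 * 0.007 / 0.00345,
               tolerance = 1e-12)
  expect_equal(reynolds(cfg, 0.5), 1065, tolerance = 0.001)
})

test_that("intrusion-curve generator hits the configured totals", {
  curve <- gen_intrusion_curve(list(median_um = 100, sdlog = 0.5,
                                    weights = 1),
                               porosity = 0.967, bulk_density = 34.2)
  expect_equal(max(curve$cumulative_volume), 0.967 / 0.0342,
               tolerance = 1e-6)
  expect_equal(porosity(curve), 96.7, tolerance = 0.05)
  tiny <- gen_intrusion_curve(list(median_um = 10, sdlog = 0.3, weights = 1),
                              porosity = 1e-6, bulk_density = 100)
  expect_lt(porosity(tiny), 1e-3)
  expect_lt(diff(range(tiny$cumulative_volume)), 1e-5)
  expect_warning(
    gen_intrusion_curve(list(median_um = 900, sdlog = 1, weights = 1),
                        porosity = 0.5, bulk_density = 100),
    "detection range")
})
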