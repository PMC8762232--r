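test_that("rms matches closed forms", {
  expect_equal(rms(tone_trace(10)), 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(rms(signal_trace(rep(0, 100), 100)), 0)
  # scale fixture: audio rescaled to a target whole-trace RMS round-trips
  cfg <- generator_config(seed = 2, duration = 3)
  au <- gen_pt_audio(cfg, 60)
  sc <- signal_trace(au$samples * (0.0032 / rms(au)), au$rate, unit = "Pa")
  expect_equal(rms(sc), 0.0032, tolerance = 1e-6)
  # windowed rms of a constant is the constant
  expect_equal(rms(signal_trace(rep(2, 1000), 1000), window = 0.1),
               rep(2, 10))
  expect_error(rms(tone_trace(10, duration = 1), window = 2), "window")
})

test_that("dB SPL conversion matches its definition and inverts", {
  expect_equal(to_db_spl(20e-6), 0)
  expect_equal(to_db_spl(2), 100)
  expect_equal(from_db_spl(64.0), 0.0317, tolerance = 1e-3)
  expect_error(to_db_spl(0), "positive")
  lv <- c(-20, 0, 35.2, 64, 120)
  expect_equal(to_db_spl(from_db_spl(lv)), lv, tolerance = 1e-9)
})

test_that("microphone calibration applies the -34 dB re 1 V/Pa sensitivity", {
  v <- signal_trace(c(0.1, -0.1, 0.05), rate = 10, unit = "volts",
                    sensitivity = -34)
  p <- calibrate_pressure(v)
  expect_equal(p$unit, "Pa")
  expect_equal(p$samples, v$samples / 10^(-34 / 20))
  expect_error(calibrate_pressure(p), "volts")
})

test_that("stft localizes tones, tracks a chirp, and conserves energy", {
  tr <- tone_trace(50, duration = 2, rate = 1000)
  sg <- stft(tr, window_length = 256, hop = 128)
  ridge <- sg$frequencies[apply(sg$magnitudes_db, 1L, which.max)]
  expect_true(all(abs(ridge - 50) <= diff(sg$frequencies[1:2])))
  # silence clamps at the floor instead of -Inf
  sg0 <- stft(signal_trace(rep(0, 512), 1000), window_length = 256)
  expect_true(all(is.finite(sg0$magnitudes_db)))
  expect_equal(max(sg0$magnitudes_db), -120)
  # linear chirp: ridge frequency increases monotonically
  t <- seq(0, 4 - 1e-3, by = 1e-3)
  chirp <- signal_trace(sin(2 * pi * (10 * t + (90 / 8) * t^2)), 1000)
  sgc <- stft(chirp, window_length = 512, hop = 256)
  ridgec <- sgc$frequencies[apply(sgc$magnitudes_db, 1L, which.max)]
  expect_true(all(diff(ridgec) >= 0))
  expect_gt(ridgec[length(ridgec)], ridgec[1])
  # Parseval: rectangular window, energy recovered per frame
  sgr <- stft(tr, window_length = 500, hop = 500, window = "rect")
  framed <- matrix(tr$samples[1:2000], nrow = 500)
  expect_equal(frame_energies(sgr), colSums(framed^2), tolerance = 0.01)
})

test_that("fundamental detection recovers periodicity and rejects aperiodic input", {
  expect_equal(detect_fundamental(tone_trace(100, duration = 1)), 100,
               tolerance = 0.01)
  expect_true(is.na(detect_fundamental(signal_trace(rep(1.5, 400), 100))))
  set.seed(42)
  expect_true(is.na(detect_fundamental(signal_trace(rnorm(4000), 1000))))
})

test_that("rank-sum test matches the exhaustive-enumeration oracle", {
  r <- compare_segments(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  # all identical values -> degenerate p = 1
  expect_equal(compare_segments(c(2, 2), c(2, 2, 2))$p_value, 1)
  # parameterised oracle comparison, n_a, n_b <= 6, with and without ties
  set.seed(19)
  for (i in 1:12) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    pool <- if (i %% 2 == 0) sample(1:5, na + nb, replace = TRUE) + 0
            else rnorm(na + nb)
    a <- pool[seq_len(na)]; b <- pool[-seq_len(na)]
    if (length(unique(pool)) == 1L) next
    expect_equal(compare_segments(a, b)$p_value, ranksum_oracle(a, b),
                 tolerance = 1e-12,
                 info = sprintf("case %d (na=%d nb=%d)", i, na, nb))
  }
})

test_that("tie-free exact p-values agree with the reference implementation", {
  set.seed(4)
  for (i in 1:6) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    expect_equal(compare_segments(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large-sample displacement comparison separates pre from post", {
  cfg_pre <- generator_config(seed = 21, duration = 5, noise_sd = 0.004)
  cfg_post <- generator_config(seed = 22, duration = 5, noise_sd = 0.004)
  pre <- gen_displacement_trace(cfg_pre, median_amp = 0.012)
  post <- gen_displacement_trace(cfg_post, median_amp = 0.092)
  r <- compare_segments(abs(pre$samples), abs(post$samples))
  expect_equal(r$method, "normal")
  expect_lt(r$p_value, 0.01)
})
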