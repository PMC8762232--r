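test_that("transmission loss of the identity system is exactly zero", {
  fr <- band_centers("tl13")
  n <- length(fr)
  tm <- transfer_matrix_spectrum(fr, rep(1 + 0i, n), rep(0i, n),
                                 rep(0i, n), rep(1 + 0i, n))
  expect_equal(transmission_loss(tm)$tl, rep(0, n))
  # area term: S_i / S_o = 10 adds exactly 10 dB
  tm10 <- transfer_matrix_spectrum(fr, rep(1 + 0i, n), rep(0i, n),
                                   rep(0i, n), rep(1 + 0i, n),
                                   inlet_area = 10, outlet_area = 1)
  expect_equal(transmission_loss(tm10)$tl, rep(10, n))
})

test_that("tube round trip recovers configured TL within 0.1 dB", {
  fr <- band_centers("tl13")
  # air only: TL = 0
  tl0 <- transmission_loss(tube_transfer_matrix(gen_tube_signals(NULL, fr)))
  expect_lt(max(abs(tl0$tl)), 0.1)
  # limp mass-law layer: closed-form oracle
  m <- material_spec("limp layer", 0.0033, 945.3, model = "limp")
  tl <- transmission_loss(tube_transfer_matrix(gen_tube_signals(m, fr)))
  expect_lt(max(abs(tl$tl - mass_law_tl(areal_density(m), fr,
                                        rho_air = 1.139, c = 340))), 0.1)
  # configured-TL layer round trips, and doubling the curve doubles it
  curve <- band_spectrum(seq(10, 40, length.out = 13), "tl13")
  mk <- function(cv) material_spec("conf", 0.003, 900,
                                   model = "configured_tl", tl_curve = cv)
  r1 <- transmission_loss(tube_transfer_matrix(gen_tube_signals(mk(curve), fr)))
  expect_lt(max(abs(r1$tl - curve$values)), 0.1)
  curve2 <- band_spectrum(2 * curve$values, "tl13")
  r2 <- transmission_loss(tube_transfer_matrix(gen_tube_signals(mk(curve2), fr)))
  expect_lt(max(abs(r2$tl - 2 * r1$tl)), 0.2)
  expect_error(gen_tube_signals(m, c(-100, 500)), "positive")
})

test_that("absorption factor is 1 - r and band-averages as printed", {
  expect_equal(absorption_factor(rep(1, 6))$values, rep(0, 6))
  expect_equal(absorption_factor(rep(0, 6))$values, rep(1, 6))
  a <- absorption_factor(rep(0.829, 6))
  expect_equal(mean(a$values), 0.171, tolerance = 1e-12)
  expect_error(absorption_factor(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("band averaging follows the stated conventions", {
  fr <- seq(100, 2100, by = 10)
  expect_equal(band_average(fr, rep(45.3, length(fr)), "tl13"), 45.3)
  # linear ramp over centers: mean of the interpolated center values
  centers <- band_centers("tl13")
  vals <- stats::approx(c(100, 2100), c(0, 20), xout = fr)$y
  expect_equal(band_average(fr, vals, "tl13"),
               mean(stats::approx(c(100, 2100), c(0, 20),
                                  xout = centers)$y),
               tolerance = 1e-3)
  # a value sitting exactly on a center is taken as-is
  one <- band_values(band_centers("tl13"), seq_len(13), "tl13")
  expect_identical(one$values, as.numeric(seq_len(13)))
  expect_error(band_values(c(200, 800), c(1, 2), band_set = "tl13"),
               "does not cover band center 125")
})

test_that("areal density multiplies density and thickness", {
  expect_equal(areal_density(material_spec("bone wax", 0.0033, 945.3)),
               3.119, tolerance = 1e-3)
  expect_equal(areal_density(material_spec("gelatin sponge", 0.0066, 34.2)),
               0.2257, tolerance = 1e-3)
})

test_that("mass law evaluates, slopes at 6 dB per doubling, and vanishes at m = 0", {
  expect_equal(mass_law_tl(3.119, 1000, 1.139, 340), 28.1, tolerance = 0.01)
  # doubling m in the large-argument regime adds 6.02 dB
  expect_equal(mass_law_tl(20, 1000) - mass_law_tl(10, 1000), 6.02,
               tolerance = 0.1)
  expect_equal(mass_law_tl(10, 2000) - mass_law_tl(10, 1000), 6.02,
               tolerance = 0.1)
  expect_equal(mass_law_tl(0, 1000), 0)
  # strictly increasing in f and m
  f <- seq(100, 2000, by = 100)
  expect_true(all(diff(mass_law_tl(3, f)) > 0))
  m <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(mass_law_tl(m, 500)) > 0))
})

test_that("density estimation inverts the mass law", {
  fr <- band_centers("tl13")
  curve <- band_spectrum(mass_law_tl(1.13, fr), "tl13")
  est <- estimate_density_from_tl(curve, 0.001)
  expect_equal(est$density, 1130, tolerance = 0.01)
  expect_false(est$low_confidence)
  # degenerate zero-TL curve
  z <- estimate_density_from_tl(band_spectrum(rep(0, 13), "tl13"), 0.001)
  expect_lt(z$density, 1)
  expect_true(z$low_confidence)
  # noisy curve: recovery within 15% (Monte-Carlo)
  set.seed(9)
  errs <- replicate(20, {
    noisy <- band_spectrum(mass_law_tl(1.13, fr) + rnorm(13, 0, 1), "tl13")
    estimate_density_from_tl(noisy, 0.001)$density
  })
  expect_lt(max(abs(errs - 1130) / 1130), 0.15)
})

test_that("composite stacks cascade transfer matrices correctly", {
  fr <- band_centers("tl13")
  air <- material_spec("air", 0.01, 1.139, sound_speed = 340)
  # lossless air layers are acoustically transparent, for any count
  for (k in c(1, 3)) {
    st <- reconstruction_stack(rep(list(air), k))
    expect_lt(max(abs(composite_stack_tl(st, fr)$tl)), 1e-9)
  }
  # a single-layer stack equals that layer's own transfer-matrix TL
  bw <- material_spec("bone wax", 0.0033, 945.3, model = "limp")
  single <- composite_stack_tl(reconstruction_stack(list(bw)), fr)
  direct <- transmission_loss(
    ptinsulate:::material_transfer_matrix(bw, fr, acoustic_medium()))
  expect_equal(single$tl, direct$tl, tolerance = 1e-12)
  # adding a second mass layer with an interstitial air gap raises TL at
  # 500 Hz (below the mass-air-mass resonance)
  sgs <- material_spec("solidified gelatin sponge", 0.0064, 368.9,
                       model = "limp")
  both <- composite_stack_tl(
    reconstruction_stack(list(bw, sgs), air_gaps = 0.001), 500)
  alone <- composite_stack_tl(reconstruction_stack(list(bw)), 500)
  expect_gt(both$tl, alone$tl)
})

test_that("material library ships the measured property table", {
  lib <- read_material_library()
  expect_true(all(c("gelatin_sponge", "bone_wax", "auricular_cartilage")
                  %in% names(lib)))
  expect_equal(lib$bone_wax$density, 945.3)
  expect_equal(lib$bone_wax$thickness, 0.0033)
  expect_equal(mean(lib$bone_wax$tl_curve$values), 45.3)
  expect_equal(lib$auricular_cartilage$density, 1130)
})
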