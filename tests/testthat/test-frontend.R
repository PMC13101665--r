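test_that("microphone transduction follows the sensitivity and preamp gain", {
  w <- waveform(rep(1, 2e6), 1e6) # 1 Pa constant
  v <- mic_transduce(w, frontend_config())
  expect_equal(v$samples[1], 10^(-38 / 20) * 50, tolerance = 1e-12)
  expect_equal(v$samples[1], 0.6295, tolerance = 1e-4)
  expect_true(all(mic_transduce(waveform(rep(0, 1e6), 1e6))$samples == 0))
  v2 <- mic_transduce(waveform(rep(2, 1e6), 1e6), frontend_config())
  expect_equal(v2$samples[1], 2 * v$samples[1])
})

test_that("band-pass response: passband flat, stopbands attenuated", {
  d <- design_bandpass(frontend_config(), 1e6)
  ref_db <- max(20 * log10(bandpass_response(d, seq(20e3, 70e3, by = 1e3))))
  h50 <- 20 * log10(bandpass_response(d, 50e3))
  expect_lt(abs(h50 - ref_db), 1)
  expect_lt(20 * log10(bandpass_response(d, 1e3)) - ref_db, -20)
  # the second-order low-pass at 100 kHz rolls off gently: about -8 dB one
  # half-octave out, monotonically falling beyond
  expect_lt(20 * log10(bandpass_response(d, 150e3)) - ref_db, -6)
  grid_hi <- seq(100e3, 450e3, by = 5e3)
  expect_true(all(diff(bandpass_response(d, grid_hi)) < 0))
  grid_lo <- seq(500, 10e3, by = 250)
  expect_true(all(diff(bandpass_response(d, grid_lo)) > 0))
})

test_that("passband deviation stays within 1 dB over 20-70 kHz", {
  d <- design_bandpass(frontend_config(), 1e6)
  band <- 20 * log10(bandpass_response(d, seq(20e3, 70e3, by = 500)))
  expect_lt(max(band) - min(band), 1)
})

test_that("band-pass design rejects cutoffs at or above Nyquist", {
  cfg <- frontend_config(lp_cutoff = 6e5)
  expect_error(design_bandpass(cfg, 1e6), "Nyquist")
})

test_that("front-end preserves in-band tones with derivative off", {
  cfg <- frontend_config(board_gain = 1, derivative = "off")
  w <- gen_sine(50e3, 0.5, 0.02, 1e6)
  out <- apply_frontend(mic_transduce(waveform(w$samples / (10^(-38/20) * 50), 1e6)), cfg)
  # steady-state peak within 1 dB of input peak
  tail_ss <- out$samples[seq(5000, length(out$samples))]
  expect_lt(abs(20 * log10(max(abs(tail_ss)) / 0.5)), 1)
})

test_that("gain stages scale linearly and clip at the rails", {
  w <- gen_sine(40e3, 0.05, 0.01, 1e6)
  o1 <- apply_frontend(w, frontend_config(board_gain = 1))
  o10 <- apply_frontend(w, frontend_config(board_gain = 10))
  expect_equal(o10$samples, 10 * o1$samples, tolerance = 1e-9)
  big <- gen_sine(40e3, 1, 0.01, 1e6)
  o100 <- apply_frontend(big, frontend_config(board_gain = 100))
  expect_equal(max(o100$samples), 2.5)
  expect_equal(min(o100$samples), -2.5)
  expect_true(all(abs(o100$samples) <= 2.5))
  # clipping is idempotent: re-applying the clamp changes nothing
  expect_identical(pmin(pmax(o100$samples, -2.5), 2.5), o100$samples)
})

test_that("derivative stage boosts high frequencies monotonically", {
  cfg <- frontend_config(derivative = "slope1")
  g20 <- frontend_response(cfg, 20e3)
  g80 <- frontend_response(cfg, 80e3)
  expect_gt(g80, g20)
  # emphasis also visible on waveforms through the full path
  a20 <- max(abs(apply_frontend(gen_sine(20e3, 0.01, 0.01), cfg)$samples))
  a80 <- max(abs(apply_frontend(gen_sine(80e3, 0.01, 0.01), cfg)$samples))
  expect_gt(a80, a20)
  # steeper corner settings push the knee up: slope3 boosts 80 kHz less
  cfg3 <- frontend_config(derivative = "slope3")
  expect_lt(frontend_response(cfg3, 80e3) / frontend_response(cfg3, 20e3),
            g80 / g20 + 1e-9)
})

test_that("Bode export writes an evaluable frequency/magnitude table", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_bode_csv(frontend_config(), path)
  tab <- utils::read.csv(path)
  expect_named(tab, c("freq_hz", "mag_db"))
  expect_equal(nrow(tab), 200)
  i50 <- which.min(abs(tab$freq_hz - 50e3))
  i1 <- which.min(abs(tab$freq_hz - 1e3))
  expect_gt(tab$mag_db[i50] - tab$mag_db[i1], 20)
})

test_that("frontend_config validates its fields", {
  expect_error(frontend_config(board_gain = 5), "board_gain")
  expect_error(frontend_config(derivative = "slope9"), "derivative")
  expect_error(frontend_config(hp_cutoff = 2e5), "below lp_cutoff")
})
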