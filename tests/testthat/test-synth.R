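test_that("gen_sine produces a calibrated pure tone", {
  w <- gen_sine(12000, level = 0.5, duration = 0.1, fs_model = 1e6)
  expect_s3_class(w, "waveform")
  expect_length(w$samples, 1e5)
  # DFT-oracle peak at 12 kHz
  X <- Mod(stats::fft(w$samples))
  half <- seq_len(length(X) / 2)
  peak_hz <- (which.max(X[half]) - 1) / length(X) * 1e6
  expect_equal(peak_hz, 12000, tolerance = 1e-6)
  # closed-form RMS of a sinusoid over whole periods
  expect_equal(sqrt(mean(w$samples^2)), 0.5 / sqrt(2), tolerance = 1e-6)
  # sampled grid need not hit the crest exactly; peak approaches level
  expect_equal(max(abs(w$samples)), 0.5, tolerance = 1e-3)
})

test_that("gen_sine zero level and aliasing guards", {
  expect_true(all(gen_sine(12000, 0, 0.01)$samples == 0))
  expect_error(gen_sine(6e5, 1, 0.01, fs_model = 1e6), "alias")
  expect_error(gen_sine(5e5, 1, 0.01, fs_model = 1e6), "alias")
})

test_that("spectral placement: tone peak lands within one analysis bin", {
  for (f in c(5000, 22000, 50000, 80000)) {
    w <- gen_sine(f, 1, 0.02, 1e6)
    X <- Mod(stats::fft(w$samples))
    n <- length(w$samples)
    peak_hz <- (which.max(X[seq_len(n / 2)]) - 1) / n * 1e6
    expect_lt(abs(peak_hz - f), 1e6 / n + 1e-9)
  }
})

test_that("flat22 call concentrates energy near 22 kHz", {
  spec <- call_spec("flat22", duration = 0.5)
  w <- gen_call(spec, 1e6)
  expect_gt(energy_fraction(w, 20000, 24000), 0.95)
})

test_that("chirp instantaneous frequency rises monotonically", {
  spec <- call_spec("chirp", f_start = 10000, f_end = 90000, duration = 0.1)
  w <- gen_call(spec, 1e6)
  # 2 ms windows: the sweep advances 1.6 kHz per window against a 500 Hz
  # estimator resolution, so the track must rise strictly
  track <- inst_freq_track(w, win = 0.002)
  track <- track[3:(length(track) - 2)]   # drop the ramped edges
  expect_true(all(diff(track) > 0))
  expect_lt(abs(track[1] - 10000), 12000)
  expect_gt(track[length(track)], 70000)
})

test_that("trill50 stays in the 50 kHz region and call kinds validate", {
  w <- gen_call(call_spec("trill50"), 1e6)
  expect_gt(energy_fraction(w, 40000, 60000), 0.95)
  expect_error(call_spec("warble"), "unknown kind")
  expect_error(call_spec("sine", duration = 0), "duration")
  expect_error(gen_call(call_spec("sine", duration = 1e-7)), "degenerate")
})

test_that("gen_session is deterministic and linear", {
  calls <- list(call_spec("short50", onset = 0.1),
                call_spec("flat22", onset = 0.3, duration = 0.2))
  s1 <- gen_session(calls, noise_level = 0.01, duration = 0.6, seed = 42)
  s2 <- gen_session(calls, noise_level = 0.01, duration = 0.6, seed = 42)
  expect_identical(s1$wave$samples, s2$wave$samples)
  # linearity: session minus its noise-free render equals the seeded noise
  clean <- gen_session(calls, noise_level = 0, duration = 0.6, seed = 42)
  noise_only <- gen_session(list(), noise_level = 0.01, duration = 0.6, seed = 42)
  expect_equal(s1$wave$samples, clean$wave$samples + noise_only$wave$samples,
               tolerance = 1e-12)
  expect_identical(s1$ground_truth, calls)
})

test_that("empty session is silent; misfit and overlap are caught", {
  s <- gen_session(list(), noise_level = 0, duration = 0.1)
  expect_true(all(s$wave$samples == 0))
  expect_error(gen_session(list(call_spec("flat22", onset = 0.5)), duration = 0.6),
               "does not fit")
  expect_message(
    gen_session(list(call_spec("short50", onset = 0.1),
                     call_spec("short50", onset = 0.11)), duration = 0.3),
    "overlapping")
})

test_that("session noise is shaped below 20 kHz", {
  s <- gen_session(list(), noise_level = 0.05, duration = 0.2, seed = 7)
  expect_equal(sqrt(mean(s$wave$samples^2)), 0.05, tolerance = 1e-9)
  expect_gt(energy_fraction(s$wave, 0, 25000), 0.95)
})

test_that("WAV export round-trips waveforms at float32 precision", {
  w <- gen_sine(22000, 0.3, 0.005, 1e6)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  w2 <- read_wav(path)
  expect_equal(w2$fs_model, 1e6)
  expect_equal(w2$samples, w$samples, tolerance = 1e-6)
})
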