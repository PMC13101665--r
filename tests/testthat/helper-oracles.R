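# Independent oracles used across the suite. The DFT oracle is a direct
# O(N^2) matrix product so that checks of the fixed-point FFT path never rely
# on the same transform routine as the implementation.

dft_direct <- function(x) {
  N <- length(x)
  k <- 0:(N - 1)
  W <- exp(-2i * pi * outer(k, k) / N)
  as.vector(W %*% x)
}

# spectral energy fraction of a waveform within [f_lo, f_hi], via the oracle
# periodogram at the waveform's own resolution
energy_fraction <- function(w, f_lo, f_hi) {
  x <- w$samples
  X <- stats::fft(x) # oracle for generator tests only; generators use no FFT
  n <- length(x)
  freqs <- (seq_len(n) - 1) / n * w$fs_model
  half <- freqs <= w$fs_model / 2
  p <- Mod(X[half])^2
  sum(p[freqs[half] >= f_lo & freqs[half] <= f_hi]) / sum(p)
}

# windowed argmax instantaneous-frequency estimate (phase-independent oracle)
inst_freq_track <- function(w, win = 0.001) {
  n <- length(w$samples)
  nw <- round(win * w$fs_model)
  starts <- seq(1, n - nw + 1, by = nw)
  vapply(starts, function(s) {
    seg <- w$samples[s:(s + nw - 1)]
    X <- Mod(stats::fft(seg))[seq_len(floor(nw / 2))]
    (which.max(X) - 1) * w$fs_model / nw
  }, numeric(1))
}

# shorthand: random 12-bit signed frames with moderate amplitude so the
# scaled FFT components stay well inside the +/-2047 saturation range
random_frames <- function(k, amp = 2047) {
  matrix(sample(seq(-amp, amp), 512 * k, replace = TRUE), nrow = 512)
}

run_tone_chain <- function(freq, level = 0.2, duration = 0.05,
                           board_gain = 10, window_msb = 17) {
  cfg <- frontend_config(board_gain = board_gain)
  w <- gen_sine(freq, level, duration, 1e6)
  v <- apply_frontend(mic_transduce(w, cfg), cfg)
  a <- sample_and_quantize(v)
  suppressMessages(process_frames(stream_to_frames(a), window_msb = window_msb))
}
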