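# 12-bit SAR ADC emulation: two channels sampled at 200 kS/s, unipolar code
# mapping about the mid-supply bias, and the immediate channel subtraction
# (sA - sB) that feeds the FFT pipeline.

#' Sample and quantize two channels
#'
#' Decimates the oversampled model waveforms to the 200 kS/s acquisition rate
#' (one conversion every 5 us) and quantizes each channel to a 12-bit unsigned
#' code with a mid-supply-biased unipolar mapping:
#' `code = clamp(round((v + vref/2) / vref * 4096), 0, 4095)`.
#' The channel difference `sA - sB` is computed immediately and saturated to
#' the signed 12-bit range -2048..2047 (the exact difference needs 13 bits;
#' saturation is used rather than wraparound, which would create spectral
#' artifacts). With channel B unconnected (constant), the subtraction removes
#' the static mid-supply offset of the analog electronics.
#'
#' @param wa Channel A [waveform] in volts.
#' @param wb Channel B [waveform], or `NULL` for an unconnected reference
#'   channel (constant 0 V about mid-supply). If given, it must have the same
#'   sampling rate and length as `wa`.
#' @param vref ADC reference span in volts (default 5, the single supply
#'   rail).
#' @param fs_acq Acquisition rate in Hz (fixed at 200000 in hardware);
#'   `wa$fs_model` must be an integer multiple of it.
#' @return An object of class `adc_stream`: fields `codes_a`, `codes_b`
#'   (integer 0..4095), `diff` (integer -2048..2047), `fs_acq`, `t0`.
#' @export
sample_and_quantize <- function(wa, wb = NULL, vref = 5, fs_acq = 200000) {
  if (!inherits(wa, "waveform")) stopf("sample_and_quantize: wa must be a waveform")
  ratio <- wa$fs_model / fs_acq
  if (abs(ratio - round(ratio)) > 1e-9) {
    stopf("sample_and_quantize: fs_model (%g) must be an integer multiple of fs_acq (%g)",
          wa$fs_model, fs_acq)
  }
  ratio <- round(ratio)
  if (is.null(wb)) {
    vb_full <- numeric(length(wa$samples))
  } else {
    if (!inherits(wb, "waveform")) stopf("sample_and_quantize: wb must be a waveform")
    if (wb$fs_model != wa$fs_model || length(wb$samples) != length(wa$samples) ||
        abs(wb$t0 - wa$t0) > 1e-12) {
      stopf("sample_and_quantize: channel waveforms cover different extents")
    }
    vb_full <- wb$samples
  }
  idx <- seq(1, length(wa$samples), by = ratio)
  quant <- function(v) {
    as.integer(clamp(round_half_away((v + vref / 2) / vref * 4096), 0, 4095))
  }
  ca <- quant(wa$samples[idx])
  cb <- quant(vb_full[idx])
  d <- as.integer(clamp(ca - cb, -2048L, 2047L))
  structure(list(codes_a = ca, codes_b = cb, diff = d,
                 fs_acq = fs_acq, t0 = wa$t0),
            class = "adc_stream")
}

#' @export
print.adc_stream <- function(x, ...) {
  cat(sprintf("<adc_stream> %d samples @ %g kS/s (%.4f s), diff range [%d, %d]\n",
              length(x$diff), x$fs_acq / 1000, length(x$diff) / x$fs_acq,
              min(x$diff), max(x$diff)))
  invisible(x)
}

#' Export the subtracted stream as raw 16-bit samples
#'
#' Writes `diff` as little-endian signed 16-bit integers for external
#' inspection.
#'
#' @param s An `adc_stream`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adc_raw <- function(s, path) {
  if (!inherits(s, "adc_stream")) stopf("write_adc_raw: not an adc_stream")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(s$diff, con, size = 2, endian = "little")
  invisible(path)
}

#' Group the subtracted stream into FFT frames
#'
#' Cuts `diff` into consecutive non-overlapping blocks of `N` samples, the
#' unit consumed by the streaming FFT. A trailing remainder shorter than `N`
#' is discarded with a log entry, mirroring a streaming FIFO that only
#' releases complete frames. Frame `k` (0-based) covers the time interval
#' `[k * N/fs_acq, (k+1) * N/fs_acq)` — 2.56 ms per frame at the defaults.
#'
#' @param s An `adc_stream`.
#' @param N Frame length in samples (default 512).
#' @return An integer matrix with `N` rows, one column per frame, with
#'   attributes `fs_acq` and `t0`.
#' @export
stream_to_frames <- function(s, N = 512) {
  if (!inherits(s, "adc_stream")) stopf("stream_to_frames: not an adc_stream")
  n <- length(s$diff)
  if (n < N) stopf("stream_to_frames: need at least %d samples, got %d", N, n)
  k <- n %/% N
  rem <- n %% N
  if (rem > 0) {
    log_event("adc", sprintf("dropping trailing remainder of %d samples (< one %d-sample frame)",
                             rem, N))
  }
  frames <- matrix(s$diff[seq_len(k * N)], nrow = N)
  attr(frames, "fs_acq") <- s$fs_acq
  attr(frames, "t0") <- s$t0
  frames
}
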