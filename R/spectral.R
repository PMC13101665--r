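# Firmware spectral datapath: 512-point FFT on real input frames, fixed-point
# power P = Re^2 + Im^2 inside a 24-bit budget, retention of the first 256
# bins (0..Fs/2), and selection of a 12-bit output window from the 24-bit
# power word.

FFT_N <- 512L
HALF_BINS <- 256L

saturate_component <- function(x) clamp(round_half_away(x), -2047, 2047)

#' Fixed-point 512-point FFT of one frame
#'
#' Models the streaming FFT core on real input (imaginary part fixed to
#' zero): the DFT is computed in natural bin order, each complex component is
#' scaled by 2^-9 (divide by 512), rounded half-away-from-zero and saturated
#' to signed 12-bit (-2047..2047). The component width guarantees that
#' `Re^2 + Im^2` always fits the 24-bit power registers. The exact internal
#' fixed-point format of the hardware core is not published; this scaling is
#' the package's reference behaviour.
#'
#' @param frame Integer/numeric vector of exactly 512 signed samples.
#' @return An object of class `complex_bins`: list with `re`, `im` (length
#'   512) and `scale_shift = 9`.
#' @export
fft512 <- function(frame) {
  if (length(frame) != FFT_N) {
    stopf("fft512: frame must have exactly %d samples (got %d)", FFT_N,
          length(frame))
  }
  X <- stats::fft(as.numeric(frame)) / FFT_N
  structure(list(re = saturate_component(Re(X)),
                 im = saturate_component(Im(X)),
                 scale_shift = 9L),
            class = "complex_bins")
}

# vectorized transform of many frames (columns); the per-frame semantics are
# exactly fft512()
fft_frames <- function(frames) {
  stopifnot(is.matrix(frames), nrow(frames) == FFT_N)
  X <- stats::mvfft(frames * 1.0) / FFT_N
  list(re = saturate_component(Re(X)), im = saturate_component(Im(X)))
}

#' Per-bin power from fixed-point FFT components
#'
#' `p24[i] = re[i]^2 + im[i]^2`. With components bounded by 2047 the worst
#' case is 2 * 2047^2 = 8,380,418 < 2^24, so the 24-bit datapath cannot
#' overflow.
#'
#' @param c A `complex_bins` object from [fft512()].
#' @return Numeric vector of 512 unsigned 24-bit power values (class
#'   `power_frame`).
#' @export
power_frame <- function(c) {
  if (!inherits(c, "complex_bins")) stopf("power_frame: input must be complex_bins")
  structure(c$re^2 + c$im^2, class = "power_frame")
}

#' Retain the non-redundant half spectrum
#'
#' For real input the upper 256 bins mirror the lower ones, so only bins
#' 0..255 (0 to Fs/2, i.e. 0-100 kHz at 200 kS/s) are kept; the symmetric
#' half is dropped. This is the 50% storage reduction of the design.
#'
#' @param p A vector of 512 power values (e.g. a `power_frame`).
#' @return The first 256 values, in order.
#' @export
half_spectrum <- function(p) {
  if (length(p) != FFT_N) stopf("half_spectrum: expected %d power values", FFT_N)
  as.numeric(p[seq_len(HALF_BINS)])
}

#' Select the 12-bit output window from a 24-bit power value
#'
#' The hardware transmits 12 of the 24 power bits; which 12 are taken trades
#' sensitivity against headroom. The window covers bits
#' `window_msb .. window_msb - 11`; if any bit above `window_msb` is set the
#' result saturates to 4095.
#'
#' @param p24 Numeric vector of 24-bit power values (0 .. 2^24 - 1).
#' @param window_msb Most significant selected bit, 6..23 (default 17).
#' @return Integer vector of 12-bit values 0..4095.
#' @export
select_output_bits <- function(p24, window_msb = 17) {
  if (!is.numeric(window_msb) || window_msb < 6 || window_msb > 23) {
    stopf("select_output_bits: window_msb must lie in 6..23 (got %s)",
          toString(window_msb))
  }
  if (any(p24 < 0 | p24 >= 2^24)) stopf("select_output_bits: p24 out of 24-bit range")
  shift <- window_msb - 11
  as.integer(pmin(p24 %/% 2^shift, 4095))
}

#' Run frames through the full spectral pipeline
#'
#' Applies [fft512()] scaling, [power_frame()], [half_spectrum()] and
#' [select_output_bits()] to every frame, producing the 256-bin 12-bit
#' spectral frames the serializer transmits. Bin `i` corresponds to frequency
#' `i * fs_acq / 512` (390.625 Hz per bin at 200 kS/s); frame `k` starts at
#' `t0 + k * 512 / fs_acq`.
#'
#' @param frames Integer matrix of 512-sample frames (columns), e.g. from
#'   [stream_to_frames()].
#' @param window_msb Output bit window, see [select_output_bits()].
#' @param fs_acq Acquisition rate in Hz.
#' @param t0 Time of the first sample, seconds.
#' @return An object of class `spectral_frames`: `bins` (256 x k integer
#'   matrix), `frame_index` (0-based), `t` (frame start times), `fs_acq`,
#'   `window_msb`.
#' @export
process_frames <- function(frames, window_msb = 17, fs_acq = NULL, t0 = NULL) {
  fs_acq <- fs_acq %||% attr(frames, "fs_acq") %||% 200000
  t0 <- t0 %||% attr(frames, "t0") %||% 0
  cb <- fft_frames(frames)
  p24 <- cb$re^2 + cb$im^2
  half <- p24[seq_len(HALF_BINS), , drop = FALSE]
  bins <- matrix(select_output_bits(as.numeric(half), window_msb),
                 nrow = HALF_BINS)
  k <- ncol(bins)
  structure(list(bins = bins, frame_index = seq_len(k) - 1L,
                 t = t0 + (seq_len(k) - 1) * FFT_N / fs_acq,
                 fs_acq = fs_acq, window_msb = window_msb),
            class = "spectral_frames")
}

#' @export
print.spectral_frames <- function(x, ...) {
  cat(sprintf("<spectral_frames> %d frames x %d bins, df = %g Hz, dt = %g ms, window_msb = %d\n",
              ncol(x$bins), nrow(x$bins), x$fs_acq / FFT_N,
              1000 * FFT_N / x$fs_acq, x$window_msb))
  invisible(x)
}
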