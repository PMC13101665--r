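# Analog front-end model: MEMS microphone sensitivity + fixed preamp, then the
# analog signal board (band-pass, optional derivative pre-emphasis, adjustable
# gain, rail clipping) as a volts-in/volts-out transform on oversampled
# waveforms.

#' Analog front-end configuration
#'
#' Parameters of the microphone stage and the analog signal board. The
#' microphone capsule is specified at -38 dBV/Pa with a fixed on-board preamp
#' gain of 50; the board adds a band-pass of roughly 10-100 kHz (active
#' second-order Butterworth sections), an optional derivative stage whose gain
#' rises with frequency (+20 dB/decade above a per-slope corner), a selectable
#' gain of x1/x10/x100, and hard clipping at the supply rails (+/-2.5 V about
#' the 5 V mid-supply bias).
#'
#' @param mic_sensitivity Microphone sensitivity in dBV/Pa (default -38).
#' @param preamp_gain Fixed preamplifier gain (default 50).
#' @param board_gain Board gain, one of 1, 10, 100.
#' @param derivative Derivative stage setting: `"off"`, `"slope1"`, `"slope2"`
#'   or `"slope3"`. Corner frequencies default to 10/20/40 kHz; the hardware
#'   exposes three jumper positions without published values, so these are
#'   configurable placeholders.
#' @param hp_cutoff High-pass cutoff in Hz (default 10000).
#' @param lp_cutoff Low-pass cutoff in Hz (default 100000).
#' @param rail Clipping rail in volts about mid-supply (default 2.5).
#' @param hp_sections Number of cascaded second-order high-pass sections
#'   (default 2, i.e. 4th-order total; set 1 for a single section).
#' @param lp_sections Number of cascaded second-order low-pass sections
#'   (default 1).
#' @param deriv_corners Named corner frequencies (Hz) for the three slopes.
#' @return An object of class `frontend_config`.
#' @export
frontend_config <- function(mic_sensitivity = -38, preamp_gain = 50,
                            board_gain = 1, derivative = "off",
                            hp_cutoff = 10000, lp_cutoff = 100000,
                            rail = 2.5, hp_sections = 2, lp_sections = 1,
                            deriv_corners = c(slope1 = 10000, slope2 = 20000,
                                              slope3 = 40000)) {
  if (!(board_gain %in% c(1, 10, 100))) {
    stopf("frontend_config: board_gain must be 1, 10 or 100 (got %g)", board_gain)
  }
  if (!(derivative %in% c("off", "slope1", "slope2", "slope3"))) {
    stopf("frontend_config: unknown derivative setting '%s'", derivative)
  }
  if (hp_cutoff >= lp_cutoff) {
    stopf("frontend_config: hp_cutoff (%g) must be below lp_cutoff (%g)",
          hp_cutoff, lp_cutoff)
  }
  structure(list(mic_sensitivity = mic_sensitivity, preamp_gain = preamp_gain,
                 board_gain = board_gain, derivative = derivative,
                 hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff, rail = rail,
                 hp_sections = as.integer(hp_sections),
                 lp_sections = as.integer(lp_sections),
                 deriv_corners = deriv_corners),
            class = "frontend_config")
}

#' @export
print.frontend_config <- function(x, ...) {
  cat(sprintf(paste0("<frontend_config> mic %g dBV/Pa x preamp %g; band-pass ",
                     "%g-%g Hz (%dx HP2 + %dx LP2); derivative %s; gain x%g; ",
                     "rail +/-%g V\n"),
              x$mic_sensitivity, x$preamp_gain, x$hp_cutoff, x$lp_cutoff,
              x$hp_sections, x$lp_sections, x$derivative, x$board_gain, x$rail))
  invisible(x)
}

#' Microphone transduction
#'
#' Converts sound pressure to the preamplified voltage presented to the analog
#' board: `v = p * 10^(sensitivity_dBV/20) * preamp_gain`. A purely linear
#' stage; 1 Pa at the defaults gives about 0.629 V.
#'
#' @param pressure A [waveform] in pascals.
#' @param cfg A [frontend_config].
#' @return A [waveform] in volts.
#' @export
mic_transduce <- function(pressure, cfg = frontend_config()) {
  if (!inherits(pressure, "waveform")) stopf("mic_transduce: input must be a waveform")
  g <- 10^(cfg$mic_sensitivity / 20) * cfg$preamp_gain
  waveform(pressure$samples * g, pressure$fs_model, pressure$t0)
}

#' Design the board band-pass filter
#'
#' Builds the cascade of digital Butterworth biquads modelling the analog
#' band-pass: `hp_sections` second-order high-pass sections at `hp_cutoff` and
#' `lp_sections` second-order low-pass sections at `lp_cutoff`, designed by
#' bilinear transform at the model rate.
#'
#' @param cfg A [frontend_config].
#' @param fs_model Model sampling rate in Hz; `lp_cutoff` must be below
#'   `fs_model / 2`.
#' @return An object of class `bandpass_design`: list of `sections`
#'   (each with `b`, `a` coefficients) plus `fs`.
#' @seealso [bandpass_response()] to evaluate the magnitude response.
#' @export
design_bandpass <- function(cfg, fs_model = 1e6) {
  if (cfg$lp_cutoff >= fs_model / 2) {
    stopf("design_bandpass: lp_cutoff %g Hz >= Nyquist %g Hz", cfg$lp_cutoff,
          fs_model / 2)
  }
  hp <- signal::butter(2, cfg$hp_cutoff / (fs_model / 2), type = "high")
  lp <- signal::butter(2, cfg$lp_cutoff / (fs_model / 2), type = "low")
  sections <- c(
    rep(list(list(b = hp$b, a = hp$a)), cfg$hp_sections),
    rep(list(list(b = lp$b, a = lp$a)), cfg$lp_sections)
  )
  structure(list(sections = sections, fs = fs_model), class = "bandpass_design")
}

# magnitude of one rational section at normalized angular frequencies w
section_response <- function(sec, w) {
  zb <- exp(-1i * outer(w, seq_along(sec$b) - 1))
  za <- exp(-1i * outer(w, seq_along(sec$a) - 1))
  as.vector((zb %*% sec$b) / (za %*% sec$a))
}

#' Evaluate the band-pass magnitude response
#'
#' @param design A `bandpass_design` from [design_bandpass()].
#' @param freqs Frequencies in Hz.
#' @return Numeric vector of linear magnitude |H(f)|.
#' @export
bandpass_response <- function(design, freqs) {
  w <- 2 * pi * freqs / design$fs
  H <- rep(1 + 0i, length(w))
  for (sec in design$sections) H <- H * section_response(sec, w)
  Mod(H)
}

# derivative stage H(s) = 1 + s/wc discretized by bilinear transform: unity
# gain at DC, +20 dB/decade above the corner
deriv_coeffs <- function(fc, fs) {
  K <- 2 * fs / (2 * pi * fc)
  list(b = c(1 + K, 1 - K), a = c(1, 1))
}

#' Full front-end magnitude response
#'
#' Band-pass times optional derivative emphasis times board gain (clipping is
#' amplitude-dependent and excluded). Used for Bode-style exports.
#'
#' @param cfg A [frontend_config].
#' @param freqs Frequencies in Hz.
#' @param fs_model Model sampling rate in Hz.
#' @return Numeric vector of linear magnitude.
#' @export
frontend_response <- function(cfg, freqs, fs_model = 1e6) {
  H <- bandpass_response(design_bandpass(cfg, fs_model), freqs)
  if (cfg$derivative != "off") {
    fc <- cfg$deriv_corners[[cfg$derivative]]
    H <- H * Mod(section_response(deriv_coeffs(fc, fs_model),
                                  2 * pi * freqs / fs_model))
  }
  H * cfg$board_gain
}

#' Export a Bode magnitude table
#'
#' Writes a two-column CSV (`freq_hz`, `mag_db`) of the front-end response on
#' a log-spaced grid, for comparison with bench Bode measurements.
#'
#' @param cfg A [frontend_config].
#' @param path Output CSV path.
#' @param fs_model Model sampling rate in Hz.
#' @param f_min,f_max Grid limits in Hz.
#' @param n_points Number of grid points.
#' @return `path`, invisibly.
#' @export
write_bode_csv <- function(cfg, path, fs_model = 1e6, f_min = 1000,
                           f_max = 200000, n_points = 200) {
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_points))
  mag <- frontend_response(cfg, freqs, fs_model)
  utils::write.csv(data.frame(freq_hz = freqs, mag_db = 20 * log10(mag)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Apply the analog signal board to a waveform
#'
#' Signal path: band-pass filter, then (unless bypassed) the derivative
#' emphasis stage, then the selected board gain, then hard clipping at the
#' supply rails. Input is the preamplified microphone voltage.
#'
#' @param w A [waveform] in volts.
#' @param cfg A [frontend_config].
#' @return A [waveform] in volts, bounded by `+/-cfg$rail`.
#' @export
apply_frontend <- function(w, cfg = frontend_config()) {
  if (!inherits(w, "waveform")) stopf("apply_frontend: input must be a waveform")
  d <- design_bandpass(cfg, w$fs_model)
  x <- w$samples
  for (sec in d$sections) x <- as.numeric(signal::filter(sec$b, sec$a, x))
  if (cfg$derivative != "off") {
    fc <- cfg$deriv_corners[[cfg$derivative]]
    dc <- deriv_coeffs(fc, w$fs_model)
    x <- as.numeric(signal::filter(dc$b, dc$a, x))
  }
  x <- x * cfg$board_gain
  x <- clamp(x, -cfg$rail, cfg$rail)
  waveform(x, w$fs_model, w$t0)
}
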