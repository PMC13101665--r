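# Synthetic acoustic inputs: pure tones, rat-call surrogates and full test
# sessions. Everything downstream of the microphone is testable without
# hardware because these generators stand in for the acoustic scene.

#' Waveform container
#'
#' A regularly sampled signal segment used throughout the analog part of the
#' chain. The model sampling rate is deliberately far above the 200 kS/s
#' acquisition rate: the analog low-pass sits at 100 kHz, exactly the
#' acquisition Nyquist frequency, so the analog chain can only be modelled on
#' an oversampled grid and is decimated to 200 kS/s afterwards by the ADC
#' model.
#'
#' @param samples Numeric vector of sample values (volts, or pascals before
#'   the microphone).
#' @param fs_model Model sampling rate in Hz; must be at least 1e6.
#' @param t0 Start time of the first sample in seconds.
#' @return An object of class `waveform`: a list with fields `samples`,
#'   `fs_model`, `t0`.
#' @seealso [gen_sine()], [gen_call()], [gen_session()]
#' @export
waveform <- function(samples, fs_model, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stopf("waveform: need at least one sample")
  if (!all(is.finite(samples))) stopf("waveform: all samples must be finite")
  if (!is.finite(fs_model) || fs_model < 1e6) {
    stopf("waveform: fs_model must be >= 1e6 Hz (got %g)", fs_model)
  }
  structure(list(samples = samples, fs_model = fs_model, t0 = t0),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.4f s), t0 = %g s, range [%.4g, %.4g]\n",
              length(x$samples), x$fs_model, length(x$samples) / x$fs_model,
              x$t0, min(x$samples), max(x$samples)))
  invisible(x)
}

#' Rat-call specification
#'
#' Describes one synthetic call. `flat22` is the long constant-frequency
#' ~22 kHz call family; `short50` a brief ~50 kHz tone; `trill50` a
#' sinusoidally frequency-modulated ~50 kHz call; `sine` a plain tone at
#' `f_start`; `chirp` a linear sweep from `f_start` to `f_end`. Defaults for
#' the stereotyped kinds follow the published spectro-temporal ranges of rat
#' ultrasonic vocalizations (22 kHz calls lasting hundreds of milliseconds,
#' 50 kHz calls tens of milliseconds).
#'
#' @param kind One of `"flat22"`, `"short50"`, `"trill50"`, `"sine"`,
#'   `"chirp"`.
#' @param f_start,f_end Frequencies in Hz (0 < f <= 100000). `f_end` is only
#'   used by `chirp`.
#' @param onset Call onset within a session, seconds.
#' @param duration Call duration in seconds (> 0). If `NULL`, a per-kind
#'   default is used: 0.8 s for `flat22`, 0.03 s for `short50`, 0.05 s for
#'   `trill50`, 0.1 s otherwise.
#' @param level Peak amplitude (pascals for acoustic input).
#' @return An object of class `call_spec`.
#' @export
call_spec <- function(kind, f_start = NULL, f_end = NULL, onset = 0,
                      duration = NULL, level = 0.1) {
  kinds <- c("flat22", "short50", "trill50", "sine", "chirp")
  if (!is.character(kind) || !(kind %in% kinds)) {
    stopf("call_spec: unknown kind '%s'", as.character(kind)[1])
  }
  f_start <- f_start %||% switch(kind,
    flat22 = 22000, short50 = 50000, trill50 = 50000, sine = 50000,
    chirp = 20000)
  f_end <- f_end %||% if (kind == "chirp") 80000 else f_start
  duration <- duration %||% switch(kind,
    flat22 = 0.8, short50 = 0.03, trill50 = 0.05, 0.1)
  if (!is.finite(duration) || duration <= 0) {
    stopf("call_spec: duration must be > 0 (got %g)", duration)
  }
  if (f_start <= 0 || f_start > 1e5 || f_end <= 0 || f_end > 1e5) {
    stopf("call_spec: frequencies must lie in (0, 100000] Hz")
  }
  structure(list(kind = kind, f_start = f_start, f_end = f_end,
                 onset = onset, duration = duration, level = level),
            class = "call_spec")
}

#' @export
print.call_spec <- function(x, ...) {
  cat(sprintf("<call_spec> %s: %g->%g Hz, onset %g s, duration %g s, level %g\n",
              x$kind, x$f_start, x$f_end, x$onset, x$duration, x$level))
  invisible(x)
}

#' Generate a pure sinusoid
#'
#' Deterministic test tone with phase zero at `t0`, the shape used to validate
#' the acquisition chain (a 12 kHz sinusoid lands in FFT bin 31 at the
#' 390.625 Hz analysis resolution).
#'
#' @param freq Tone frequency in Hz; must satisfy `freq < fs_model / 2`.
#' @param level Peak amplitude.
#' @param duration Duration in seconds.
#' @param fs_model Model sampling rate in Hz (default 1 MS/s).
#' @param t0 Start time in seconds.
#' @return A [waveform].
#' @examples
#' w <- gen_sine(12000, level = 0.5, duration = 0.01)
#' @export
gen_sine <- function(freq, level, duration, fs_model = 1e6, t0 = 0) {
  if (!is.finite(freq) || freq <= 0 || freq >= fs_model / 2) {
    stopf("gen_sine: freq must lie in (0, fs_model/2); %g Hz would alias", freq)
  }
  if (duration <= 0) stopf("gen_sine: duration must be > 0")
  n <- round(duration * fs_model)
  t <- (seq_len(n) - 1) / fs_model
  waveform(level * sin(2 * pi * freq * t), fs_model, t0)
}

# raised-cosine on/off ramps (1 ms) so synthetic calls do not splatter energy
# across the band through hard edges
raised_cosine_envelope <- function(n, fs, ramp = 0.001) {
  env <- rep(1, n)
  nr <- min(round(ramp * fs), floor(n / 2))
  if (nr > 0) {
    r <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    env[seq_len(nr)] <- r
    env[n + 1 - seq_len(nr)] <- r
  }
  env
}

#' Generate one synthetic rat call
#'
#' Renders a [call_spec] to a waveform: constant tones for `flat22`/`short50`/
#' `sine`, a sinusoidal frequency modulation around 50 kHz for `trill50`
#' (default depth 8 kHz, rate 80 Hz), and a linear sweep for `chirp`. All
#' kinds get 1 ms raised-cosine onset/offset ramps.
#'
#' @param spec A [call_spec].
#' @param fs_model Model sampling rate in Hz.
#' @param fm_depth,fm_rate Frequency-modulation depth (Hz) and rate (Hz) for
#'   `trill50`.
#' @return A [waveform] starting at `spec$onset`.
#' @export
gen_call <- function(spec, fs_model = 1e6, fm_depth = 8000, fm_rate = 80) {
  if (!inherits(spec, "call_spec")) stopf("gen_call: spec must be a call_spec")
  n <- round(spec$duration * fs_model)
  if (n < 2) stopf("gen_call: degenerate duration %g s", spec$duration)
  t <- (seq_len(n) - 1) / fs_model
  f_inst <- switch(spec$kind,
    flat22  = rep(spec$f_start, n),
    short50 = rep(spec$f_start, n),
    sine    = rep(spec$f_start, n),
    trill50 = spec$f_start + fm_depth * sin(2 * pi * fm_rate * t),
    chirp   = spec$f_start + (spec$f_end - spec$f_start) * t / spec$duration)
  phase <- 2 * pi * cumsum(f_inst) / fs_model
  env <- raised_cosine_envelope(n, fs_model)
  waveform(spec$level * env * sin(phase), fs_model, spec$onset)
}

#' Generate a full synthetic recording session
#'
#' Sums calls at their onsets over a ventilation-like background: seeded
#' Gaussian noise shaped by a cascade of two second-order low-pass sections
#' at 20 kHz, mimicking the
#' broadband room/ventilation noise that dominates below the ultrasonic band
#' in real recordings. The returned ground truth drives detector tests.
#'
#' @param calls List of [call_spec] objects; all must fit inside `duration`.
#' @param noise_level Background RMS level after shaping (same unit as call
#'   levels); 0 disables noise.
#' @param duration Session duration in seconds.
#' @param seed Integer seed; identical seed and specs give a bitwise-identical
#'   waveform. `NULL` draws from the current RNG stream (used when an outer
#'   caller manages the single session seed).
#' @param fs_model Model sampling rate in Hz.
#' @param noise_cutoff Low-pass corner of the noise shaping filter, Hz.
#' @return A list with `wave` (the [waveform]) and `ground_truth` (the call
#'   list).
#' @export
gen_session <- function(calls, noise_level = 0, duration = 1, seed = 1,
                        fs_model = 1e6, noise_cutoff = 20000) {
  n <- round(duration * fs_model)
  x <- numeric(n)
  for (spec in calls) {
    if (!inherits(spec, "call_spec")) stopf("gen_session: calls must be call_spec objects")
    if (spec$onset < 0 || spec$onset + spec$duration > duration + 1e-12) {
      stopf("gen_session: call (%s, onset %g s, duration %g s) does not fit in %g s",
            spec$kind, spec$onset, spec$duration, duration)
    }
  }
  if (length(calls) >= 2) {
    on_t <- vapply(calls, `[[`, numeric(1), "onset")
    off_t <- on_t + vapply(calls, `[[`, numeric(1), "duration")
    o <- order(on_t)
    if (any(on_t[o][-1] < off_t[o][-length(o)])) {
      log_event("synth", "overlapping calls in session", "WARN")
    }
  }
  for (spec in calls) {
    w <- gen_call(spec, fs_model)
    i0 <- round(spec$onset * fs_model)
    idx <- i0 + seq_along(w$samples)
    idx <- idx[idx <= n]
    x[idx] <- x[idx] + w$samples[seq_along(idx)]
  }
  if (noise_level > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old_seed, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    # two cascaded second-order sections: a 4th-order rolloff keeps the
    # surrogate's energy essentially confined below the cutoff
    lp <- signal::butter(2, noise_cutoff / (fs_model / 2), type = "low")
    noise <- as.numeric(signal::filter(lp, stats::rnorm(n)))
    noise <- as.numeric(signal::filter(lp, noise))
    noise <- noise * (noise_level / sqrt(mean(noise^2)))
    x <- x + noise
  }
  list(wave = waveform(x, fs_model, 0), ground_truth = calls)
}

#' Write a waveform as a float32 WAV file
#'
#' Minimal RIFF/WAVE writer (IEEE float, mono) so model waveforms can be
#' inspected in standard audio tools. The header carries `fs_model` as the
#' sample rate.
#'
#' @param w A [waveform].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  if (!inherits(w, "waveform")) stopf("write_wav: not a waveform")
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(w$samples)
  data_bytes <- n * 4L
  fs <- as.integer(round(w$fs_model))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(w$samples, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a float32 WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return A [waveform].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stopf("read_wav: %s is not a RIFF/WAVE file", path)
  }
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stopf("read_wav: no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = sz - 8)
      if (fmt[1] != 3L || fmt[2] != 1L) stopf("read_wav: only mono float32 supported")
    } else if (identical(id, "data")) {
      x <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
      return(waveform(x, fs))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}
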