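---
title: "Modelling an FPGA-based ultrasonic vocalization acquisition chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an FPGA-based ultrasonic vocalization acquisition chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvchain)
```

## Why simulate a recorder?

Rats vocalize in two ultrasonic families — long aversive calls near 22 kHz
and short appetitive calls near 50 kHz — and low-cost open recorders for
these signals compute spectrograms *on line*: instead of storing raw
200 kS/s audio, the hardware digitizes, transforms and transmits 256-bin
power spectra, and the host stores a CSV time–frequency table. `usvchain`
is a faithful software model of one such chain. Every stage — acoustic
synthesis, analog conditioning, 12-bit conversion, fixed-point spectral
processing, serial framing, storage and screening — is an explicit,
testable function, so the numerical contracts of the hardware design
(resolutions, bit widths, frame formats, loss behaviour) can be verified
without a soldering iron.

The chain and its fixed constants:

| stage | model | key constants |
|---|---|---|
| microphone | linear sensitivity + fixed preamp | −38 dBV/Pa, ×50 |
| analog board | Butterworth band-pass, optional pre-emphasis, gain, clipping | 10–100 kHz, ×1/×10/×100, ±2.5 V rails |
| ADC | decimation + mid-supply unipolar quantization, channel subtraction | 12 bit, 200 kS/s, 5 µs/sample |
| FFT pipeline | 512-point DFT, ÷512, round, saturate; P = Re² + Im² | 12-bit components, 24-bit power |
| buffering | keep bins 0–255 (0–100 kHz) | 50 % storage reduction |
| serial link | 6+6-bit packing, SoF flags, 8N1 | 512 bytes / 2.56 ms, 3 Mbaud |
| host | CSV (ISO-8601 ms timestamps + 256 ints), log colour map, screening | 390.625 Hz × 2.56 ms cells |

## Synthetic acoustic input

`gen_call()` renders stereotyped call surrogates: `flat22` (constant
~22 kHz, default 0.8 s), `short50` (constant ~50 kHz, 30 ms), `trill50`
(sinusoidal FM around 50 kHz, depth 8 kHz, rate 80 Hz, 50 ms) and a linear
`chirp`. The published literature specifies the *bands* and duration orders
of these calls, not waveforms, so the surrogate shapes (FM depth/rate,
durations, the 1 ms raised-cosine ramps that keep call edges from
splattering energy across the band) are package defaults, exposed as
arguments. Absolute call amplitude in pascals is deliberately nominal:
real systems of this class are not absolutely calibrated, so levels only
matter relative to noise and to the ADC span. The worked defaults
(0.1 Pa peak, board gain ×10) put a call at roughly one sixth of the ADC
span — comfortably detected, far from clipping.

`gen_session()` sums calls at their onsets over "ventilation" noise:
Gaussian noise shaped by two cascaded second-order 20 kHz low-pass
sections (4th-order rolloff, so the surrogate stays essentially below the
ultrasonic band, as room ventilation does). One seed determines the whole
session; the same seed reproduces the waveform bit for bit.

What the generator does **not** emulate: room acoustics and echoes,
microphone directivity, call amplitude statistics of real animals, cage
scratching and other impulsive broadband transients. Passing the
end-to-end tests therefore demonstrates that the *chain* is faithful, not
that the simple screening detector would meet any particular
recall/precision point on real recordings.

## The analog front-end

The model waveform rate defaults to 1 MS/s. This is deliberate: the analog
low-pass sits at 100 kHz, exactly the Nyquist frequency of the 200 kS/s
acquisition, and a digital filter with its corner *at* Nyquist is
unrealizable — so the analog chain is modelled oversampled and only then
decimated by the ADC model.

The band-pass is built from Butterworth biquads (bilinear transform at the
model rate): two second-order high-pass sections at 10 kHz and one
second-order low-pass at 100 kHz. Butterworth alignment is chosen because
the hardware's measured response is flat in the passband. A real
second-order low-pass at 100 kHz is, however, a *gentle* filter: the model
(like the analog circuit it mirrors) is about −2 dB at 90 kHz and only
−8 dB at 150 kHz. The package's property tests therefore assert what this
topology actually provides — deviation under 1 dB across 20–70 kHz, −20 dB
below 1 kHz, monotone rolloff above 100 kHz passing −6 dB by 150 kHz —
rather than a brick wall no second-order section can deliver. Users who
want a sharper anti-alias model can raise `lp_sections`.

The derivative (pre-emphasis) stage is `H(s) = 1 + s/ωc`: unity at low
frequency, +20 dB/decade above the corner. The hardware exposes three
jumper slopes without published values; the model defaults the corners to
10/20/40 kHz (`slope1..3`) and makes them configurable. Gain (×1/×10/×100)
is applied after filtering, then the signal hard-clips at ±2.5 V — the
single 5 V supply biased at mid-rail.

## ADC and fixed-point spectral pipeline

Each 5 µs conversion maps volts to a 12-bit unsigned code,
`clamp(round((v + vref/2)/vref · 4096), 0, 4095)`, on both channels; the
channel difference `sA − sB` is formed immediately and *saturated* to
−2048…2047. The exact difference needs 13 bits; saturation is preferred to
wraparound because wraparound would inject large spectral artifacts
exactly where the FFT looks. With channel B unconnected the subtraction
reduces to removing the mid-supply constant. The input-span mapping
(unipolar about mid-supply) is a recorded assumption — the converter's
configured span is not published.

Frames are 512 consecutive difference samples, non-overlapping — the
2.56 ms temporal resolution equals exactly one frame hop, which is why no
window function is applied (windowing would also change the stated
resolution identities). A trailing remainder shorter than a frame is
dropped and logged, as a streaming FIFO would.

The transform models the hardware FFT core's observable behaviour: DFT in
natural order, components scaled by 2⁻⁹ (÷512), rounded
half-away-from-zero, saturated to ±2047. The core's true internal
fixed-point format is not published; this scaling is the simplest model
consistent with the documented 24-bit no-overflow power datapath, since
2 · 2047² = 8 380 418 < 2²⁴. It is the package's declared reference
behaviour, and the oracle test bounds its deviation from an exact
floating-point DFT by the component rounding: per-bin power error at most
2 · 2047 · 0.5 + 0.5 ≈ 2048.

Of the 24 power bits, 12 are transmitted. `window_msb` (default 17, i.e.
bits 17…6) selects the window; anything overflowing the window saturates
to 4095. The default keeps the worked example's call peaks in the upper
half of the display range without saturating; it is the main sensitivity
control a user should expect to tune, exactly as the hardware's bit-subset
choice is.

Rounding is half-away-from-zero at every fixed-point site, stated once in
`round_half_away()` and applied uniformly.

## The wire format and the decoder

Each 12-bit bin becomes two bytes — six MSBs in the low part of the first,
six LSBs in the low part of the second. Bits 7–6 of every byte are flags:
set in *both* bytes of a frame's first pair (the start-of-frame marker),
clear everywhere else, so the marker cannot occur inside data. The
published description of the flag convention admits a second reading (one
flag bit per byte); this package fixes the both-bytes convention and the
decoder accepts only it. 512 bytes per frame every 2.56 ms needs
2.0 Mbit/s under 8N1 framing (10 wire bits per byte — parity is not used),
against the 3 Mbaud link: 67 % utilization.

The decoder treats corruption as data, never as an exception. It
synchronizes on flag pairs, validates that a frame's interior is
flag-free and 512 bytes long, and on any violation skips to the next
marker, logs `(byte_offset, bytes_skipped)` and substitutes zero-filled
blank frames to keep the time axis continuous. Blank count is
`ceiling(gap/512)`: a frame whose header was consumed but whose body was
damaged counts as one missing slot (a strict floor would assign *zero*
blanks to the commonest fault, a single lost byte, and shear the time
axis). A decoder started at an arbitrary offset locks within one frame
length. These properties are tested by fault injection at the loss rate
observed on real hardware (~10⁻⁶/byte) over a full 30-minute session's
byte count; the rate is an input, not a claim.

## Storage, display, screening

CSV rows are `ISO-8601 timestamp (ms precision), 256 integers`, no header
by default — directly loadable in R, Python or a spreadsheet. The dialect
(comma, `YYYY-MM-DDTHH:MM:SS.mmm`, UTC) is fixed by this package since
only the content order is specified upstream; timestamps are written from
rounded milliseconds so the round-trip is exact. Recording filenames get a
`_YYYYMMDD-HHMMSS` stamp so sessions never overwrite each other.

Display colour is `x = log2(1 + v)/12` mapped piecewise-linearly
blue→green→red, so v = 0, 63, 4095 hit pure blue, green, red: a
logarithmic map with a fixed formula standing in for the qualitative
"logarithmic blue–green–red" of the original GUI.

`screen_calls()` is intentionally the simplest detector that mirrors how
calls are judged on the live display: per-bin median over time as
background, cells ≥ 10 dB (power dB) above it inside 18–80 kHz as
candidates, runs of ≥ 10 ms as events. The thresholds are package
defaults, not published values. Against the generator's ground truth at
20 dB SNR it recovers all injected calls with onsets within a couple of
frames; that is a regression property of this detector on this generator,
not a performance claim about real recordings (for which purpose-built
segmentation tools exist).

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for
desk-scale runs: tone checks use 50–100 ms of signal (≈20–40 frames),
oracle comparisons 100 random frames against a direct O(N²) DFT,
round-trip checks 1000 random frames, the session benchmark 5 s with six
calls, and the loss audit a full 30-minute wire stream (360 MB,
703 125 frames) decoded in bookkeeping-only mode (`keep_values = FALSE`).
Determinism is end to end: one integer seed fixes session noise and fault
injection; no stage draws ambient entropy.

Degenerate inputs are rejected loudly (zero-duration calls, aliased tone
frequencies, mismatched channel extents, sub-frame streams), while
recoverable anomalies (trailing samples, malformed CSV rows, wire gaps)
are logged through stage-tagged messages and handled.

## Known limitations

* No op-amp noise, component tolerance, or impedance model; the analog
  stage is ideal apart from its transfer function and the rails.
* Channel multiplexer skew (≤2.5 µs between the two ADC channels) is
  ignored; both channels sample at the same instant, as the two streams
  are time-aligned downstream.
* The FFT core is modelled at frame granularity (one frame latency), not
  at streaming-handshake granularity.
* The serial link model carries bytes, not bits: physical-layer timing and
  USB bridge latency are out of scope, which is why byte loss is injected
  probabilistically instead of emerging from a timing model.
* The screening detector is a test instrument, not an analysis tool.
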