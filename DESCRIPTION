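Package: usvchain
Title: Simulation of a Real-Time Ultrasonic Vocalization Spectrogram
    Acquisition Chain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end software model of an FPGA-based rodent ultrasonic
    vocalization recorder. Generates synthetic rat calls (22 kHz and 50 kHz
    families) over ventilation-like background noise, models the analog
    band-pass front-end with adjustable gain and optional high-frequency
    pre-emphasis, emulates dual-channel 12-bit successive-approximation ADC
    sampling at 200 kS/s with channel subtraction, reproduces the firmware's
    streaming 512-point fixed-point FFT power pipeline (24-bit power, 256
    retained bins, 12-bit output window), implements the byte-exact serial
    frame format with start-of-frame synchronization, loss logging and
    blank-frame substitution, and mirrors the host software's CSV storage,
    logarithmic colour mapping, spectrogram rendering and 18-80 kHz call
    screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    png,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
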