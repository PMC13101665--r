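# Chain orchestration: one configuration object, the end-to-end simulation
# run (synthesis -> analog front-end -> ADC -> spectral pipeline -> serial
# codec -> CSV/PNG), and the self-check of the chain's derived constants.

#' Chain configuration
#'
#' All tunable parameters of the acquisition chain in one object. Randomness
#' anywhere in a chain run flows from the single `seed`.
#'
#' @param fs_acq Acquisition sampling rate, Hz (hardware value 200000).
#' @param N FFT length (512).
#' @param bins Retained bins; must equal `N / 2`.
#' @param baud Serial link baud rate (3e6).
#' @param frontend A [frontend_config].
#' @param window_msb 12-bit output window MSB, see [select_output_bits()].
#' @param seed Integer seed for the whole chain.
#' @param fs_model Oversampled model rate, Hz; integer multiple of `fs_acq`.
#' @param vref ADC reference span, volts.
#' @param origin Absolute time assigned to the first frame (default a fixed
#'   epoch so that runs are reproducible; pass `Sys.time()` for wall-clock
#'   stamps).
#' @param out_dir Output directory for [run_chain()] artifacts.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(fs_acq = 200000, N = 512, bins = N / 2, baud = 3e6,
                         frontend = frontend_config(), window_msb = 17,
                         seed = 1, fs_model = 1e6, vref = 5,
                         origin = as.POSIXct("2026-01-01 00:00:00", tz = "UTC"),
                         out_dir = ".") {
  if (bins != N / 2) stopf("chain_config: bins (%g) must equal N/2 (%g)", bins, N / 2)
  ratio <- fs_model / fs_acq
  if (abs(ratio - round(ratio)) > 1e-9) {
    stopf("chain_config: fs_model must be an integer multiple of fs_acq")
  }
  if (!inherits(frontend, "frontend_config")) stopf("chain_config: frontend must be a frontend_config")
  structure(list(fs_acq = fs_acq, N = as.integer(N), bins = as.integer(bins),
                 baud = baud, frontend = frontend,
                 window_msb = as.integer(window_msb), seed = as.integer(seed),
                 fs_model = fs_model, vref = vref,
                 origin = as.POSIXct(origin, tz = "UTC"), out_dir = out_dir),
            class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf("<chain_config> fs_acq %g kS/s, N = %d, %d bins, %g Mbaud, window_msb %d, seed %d\n",
              x$fs_acq / 1000, x$N, x$bins, x$baud / 1e6, x$window_msb, x$seed))
  print(x$frontend)
  invisible(x)
}

#' Save a chain configuration as YAML
#'
#' @param cfg A [chain_config].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  if (!inherits(cfg, "chain_config")) stopf("save_config: not a chain_config")
  lst <- unclass(cfg)
  lst$frontend <- unclass(lst$frontend)
  lst$frontend$deriv_corners <- as.list(lst$frontend$deriv_corners)
  lst$origin <- format(cfg$origin, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Load a chain configuration from YAML
#'
#' @param path YAML path written by [save_config()].
#' @return A [chain_config].
#' @export
load_config <- function(path) {
  lst <- yaml::read_yaml(path)
  fe <- do.call(frontend_config, c(
    lst$frontend[setdiff(names(lst$frontend), "deriv_corners")],
    list(deriv_corners = unlist(lst$frontend$deriv_corners))))
  chain_config(fs_acq = lst$fs_acq, N = lst$N, bins = lst$bins,
               baud = lst$baud, frontend = fe, window_msb = lst$window_msb,
               seed = lst$seed, fs_model = lst$fs_model, vref = lst$vref,
               origin = as.POSIXct(lst$origin, format = "%Y-%m-%dT%H:%M:%OS",
                                   tz = "UTC"),
               out_dir = lst$out_dir)
}

#' Run the full acquisition chain on a synthetic session
#'
#' Executes every stage of the chain: session synthesis, microphone
#' transduction, analog board, ADC sampling and subtraction, framing, the
#' fixed-point spectral pipeline, serial encoding, optional byte-loss fault
#' injection, stream decoding, and CSV/PNG output. Given the same
#' configuration (including seed) the outputs are byte-identical.
#'
#' @param cfg A [chain_config].
#' @param calls List of [call_spec] objects (the session content).
#' @param duration Session duration in seconds.
#' @param noise_level Background noise RMS (pascals), see [gen_session()].
#' @param fault_prob Per-byte deletion probability on the wire (default 0).
#' @param basename Stem for output files.
#' @param timestamp_names Decorate filenames with the wall-clock time via
#'   [timestamped_filename()] (default `FALSE` to keep runs reproducible).
#' @param render Also write the PNG rendering (default `TRUE`).
#' @return A list: `bin_path`, `csv_path`, `png_path`, `report` (the
#'   [decode_stream()] report), `table` (the [spectrogram_table]),
#'   `ground_truth`.
#' @export
run_chain <- function(cfg, calls, duration, noise_level = 0, fault_prob = 0,
                      basename = "session", timestamp_names = FALSE,
                      render = TRUE) {
  if (!inherits(cfg, "chain_config")) stopf("run_chain: cfg must be a chain_config")
  set.seed(cfg$seed)
  ses <- gen_session(calls, noise_level = noise_level, duration = duration,
                     seed = NULL, fs_model = cfg$fs_model)
  v_mic <- mic_transduce(ses$wave, cfg$frontend)
  v_board <- apply_frontend(v_mic, cfg$frontend)
  stream <- sample_and_quantize(v_board, NULL, vref = cfg$vref,
                                fs_acq = cfg$fs_acq)
  frames <- stream_to_frames(stream, N = cfg$N)
  spec <- process_frames(frames, window_msb = cfg$window_msb,
                         fs_acq = cfg$fs_acq)
  wire <- encode_frames(spec$bins)
  dropped <- integer(0)
  if (fault_prob > 0) {
    inj <- inject_byte_loss(wire, fault_prob)
    wire <- inj$bytes
    dropped <- inj$dropped
    log_event("chain", sprintf("fault injection dropped %d byte(s)", length(dropped)))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(cfg$out_dir, basename)
  csv_name <- paste0(stem, ".csv")
  if (timestamp_names) csv_name <- timestamped_filename(csv_name)
  bin_path <- paste0(stem, ".bin")
  png_path <- paste0(stem, ".png")
  writeBin(wire, bin_path)
  report <- decode_stream(wire, t0 = 0, frame_period = cfg$N / cfg$fs_acq)
  tab <- as_spectrogram_table(report, origin = cfg$origin)
  write_spectrogram_csv(tab, csv_name)
  if (render && nrow(tab$values) > 0) {
    render_spectrogram(tab, png_path, annotate = FALSE)
  } else {
    png_path <- NULL
  }
  list(bin_path = bin_path, csv_path = csv_name, png_path = png_path,
       report = report, table = tab, ground_truth = ses$ground_truth,
       dropped_bytes = dropped)
}

#' Validate the chain's derived constants
#'
#' Recomputes the resolution identities and budgets from the configuration:
#' bin spacing `fs_acq / N`, frame duration `N / fs_acq`, bytes per frame,
#' storage reduction from half-spectrum retention, and UART feasibility, and
#' checks them against the declared invariants.
#'
#' @param cfg A [chain_config].
#' @param quiet Suppress the printed report.
#' @return A list (class `chain_validation`) with `df_hz`, `dt_s`,
#'   `bytes_per_frame`, `storage_ratio`, `uart` and `ok`.
#' @export
validate_chain <- function(cfg = chain_config(), quiet = FALSE) {
  df <- cfg$fs_acq / cfg$N
  dt <- cfg$N / cfg$fs_acq
  bytes_per_frame <- cfg$bins * 2L
  # stored bits per frame over raw sample bits per frame (12-bit both sides)
  storage_ratio <- (cfg$bins * 12) / (cfg$N * 12)
  u <- uart_budget(cfg$baud, bytes_per_frame, dt)
  ok <- isTRUE(all.equal(cfg$bins, cfg$N / 2)) &&
    u$feasible && df > 0 && dt > 0
  res <- structure(list(df_hz = df, dt_s = dt,
                        bytes_per_frame = bytes_per_frame,
                        storage_ratio = storage_ratio, uart = u, ok = ok),
                   class = "chain_validation")
  if (!quiet) print(res)
  res
}

#' @export
print.chain_validation <- function(x, ...) {
  cat(sprintf("bin spacing      : %g Hz\n", x$df_hz))
  cat(sprintf("frame duration   : %g ms\n", 1000 * x$dt_s))
  cat(sprintf("bytes per frame  : %d\n", x$bytes_per_frame))
  cat(sprintf("storage reduction: %g%% of raw\n", 100 * x$storage_ratio))
  print(x$uart)
  cat(sprintf("overall          : %s\n", if (x$ok) "OK" else "MISMATCH"))
  invisible(x)
}
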