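# Host-side storage and display: spectrogram tables, CSV round-trip with
# absolute millisecond timestamps, timestamped output filenames, the
# logarithmic blue-green-red colour mapping, static PNG rendering, and a
# simple 18-80 kHz call screen used by end-to-end tests.

#' Spectrogram table
#'
#' The CSV/image-facing structure: one row per 2.56 ms frame, one column per
#' 390.625 Hz frequency bin, with absolute timestamps.
#'
#' @param values Integer matrix, rows = frames (time), 256 columns = bins.
#' @param origin Absolute time of the first frame (`POSIXct`, or anything
#'   [as.POSIXct()] accepts; stored in UTC).
#' @param dt Seconds per row (default 0.00256).
#' @param df Hz per column (default 390.625).
#' @param ts Optional explicit per-row `POSIXct` timestamps (defaults to
#'   `origin + (row - 1) * dt`).
#' @return An object of class `spectrogram_table` with fields `values`, `ts`,
#'   `origin`, `dt`, `df`.
#' @export
spectrogram_table <- function(values, origin = as.POSIXct("2026-01-01 00:00:00", tz = "UTC"),
                              dt = 0.00256, df = 390.625, ts = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 256L) {
    stopf("spectrogram_table: expected 256 columns, got %d", ncol(values))
  }
  storage.mode(values) <- "integer"
  origin <- as.POSIXct(origin, tz = "UTC")
  if (is.null(ts)) ts <- origin + (seq_len(nrow(values)) - 1) * dt
  if (length(ts) != nrow(values)) stopf("spectrogram_table: ts length mismatch")
  if (nrow(values) > 1 && any(diff(as.numeric(ts)) <= 0)) {
    stopf("spectrogram_table: row timestamps must be strictly increasing")
  }
  structure(list(values = values, ts = ts, origin = origin, dt = dt, df = df),
            class = "spectrogram_table")
}

#' @export
print.spectrogram_table <- function(x, ...) {
  cat(sprintf("<spectrogram_table> %d frame(s) x %d bins, dt = %g ms, df = %g Hz, origin %s\n",
              nrow(x$values), ncol(x$values), 1000 * x$dt, x$df,
              format(x$origin, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")))
  invisible(x)
}

#' Build a spectrogram table from a decode report
#'
#' @param report A `decode_report` from [decode_stream()] (decoded with
#'   `keep_values = TRUE`).
#' @param origin Absolute time of the first frame.
#' @return A [spectrogram_table]; blank frames appear as zero rows.
#' @export
as_spectrogram_table <- function(report, origin = as.POSIXct("2026-01-01 00:00:00", tz = "UTC")) {
  if (!inherits(report, "decode_report")) stopf("as_spectrogram_table: not a decode_report")
  if (is.null(report$frames)) stopf("as_spectrogram_table: report carries no values (keep_values = FALSE)")
  spectrogram_table(t(report$frames), origin = origin)
}

format_ts_ms <- function(ts) {
  ms <- round(as.numeric(ts) * 1000)
  sec <- ms %/% 1000
  rem <- ms %% 1000
  paste0(format(as.POSIXct(sec, origin = "1970-01-01", tz = "UTC"),
                "%Y-%m-%dT%H:%M:%S"),
         ".", sprintf("%03d", rem))
}

#' Write a spectrogram table as CSV
#'
#' One line per frame: an ISO-8601 timestamp with millisecond precision,
#' followed by the 256 integer bin values, comma-separated. No header row by
#' default, matching the acquisition software's storage format.
#'
#' @param tab A [spectrogram_table].
#' @param path Output path.
#' @param header Write a header row naming the columns (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_spectrogram_csv <- function(tab, path, header = FALSE) {
  if (!inherits(tab, "spectrogram_table")) stopf("write_spectrogram_csv: not a spectrogram_table")
  n <- nrow(tab$values)
  lines <- character(0)
  if (header) {
    lines <- paste(c("timestamp", sprintf("bin%03d", 0:255)), collapse = ",")
  }
  if (n == 0L) {
    log_event("record", sprintf("writing empty spectrogram table to %s", path), "WARN")
  } else {
    body <- do.call(paste, c(list(format_ts_ms(tab$ts)),
                             lapply(seq_len(256), function(j) tab$values[, j]),
                             sep = ","))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a spectrogram CSV
#'
#' Parses the dialect written by [write_spectrogram_csv()]. Malformed rows
#' (wrong field count, unparseable timestamp or values) are logged and
#' skipped; a file with zero valid rows is an error.
#'
#' @param path CSV path.
#' @return A [spectrogram_table].
#' @export
read_spectrogram_csv <- function(path) {
  if (!file.exists(path)) stopf("read_spectrogram_csv: no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && startsWith(lines[1], "timestamp")) lines <- lines[-1]
  parts <- strsplit(lines, ",", fixed = TRUE)
  keep <- vapply(parts, length, integer(1)) == 257L
  if (any(!keep)) {
    log_event("record", sprintf("skipping %d malformed row(s) in %s", sum(!keep), path), "WARN")
    parts <- parts[keep]
  }
  if (length(parts) == 0L) stopf("read_spectrogram_csv: no valid rows in %s", path)
  ts <- as.POSIXct(vapply(parts, `[[`, character(1), 1L),
                   format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  vals <- suppressWarnings(
    matrix(as.integer(unlist(lapply(parts, `[`, -1L))), ncol = 256L, byrow = TRUE))
  bad <- is.na(ts) | rowSums(is.na(vals)) > 0
  if (any(bad)) {
    log_event("record", sprintf("skipping %d unparseable row(s) in %s", sum(bad), path), "WARN")
    ts <- ts[!bad]
    vals <- vals[!bad, , drop = FALSE]
  }
  if (nrow(vals) == 0L) stopf("read_spectrogram_csv: no valid rows in %s", path)
  ts <- as.POSIXct(round(as.numeric(ts) * 1000) / 1000,
                   origin = "1970-01-01", tz = "UTC")
  spectrogram_table(vals, origin = ts[1], ts = ts)
}

#' Timestamp an output filename
#'
#' Inserts `_YYYYMMDD-HHMMSS` before the `.csv` extension so repeated
#' recordings never overwrite each other. A base without the `.csv` extension
#' gets one appended first (logged).
#'
#' @param base Base filename, normally ending in `.csv`.
#' @param t Wall-clock time (`POSIXct`).
#' @return The decorated filename.
#' @examples
#' timestamped_filename("a.csv", as.POSIXct("2026-04-12 12:00:00", tz = "UTC"))
#' @export
timestamped_filename <- function(base, t = Sys.time()) {
  if (!grepl("\\.csv$", base)) {
    log_event("record", sprintf("appending .csv extension to '%s'", base))
    base <- paste0(base, ".csv")
  }
  stamp <- format(t, "_%Y%m%d-%H%M%S")
  sub("\\.csv$", paste0(stamp, ".csv"), base)
}

#' Map a 12-bit spectral value to a display colour
#'
#' Logarithmic blue-green-red gradient: `x = log2(1 + v) / 12` in \[0, 1\],
#' then piecewise-linear blue (0,0,255) to green (0,255,0) for `x` in
#' \[0, 0.5\] and green to red (255,0,0) for `x` in \[0.5, 1\]. Value 0 is
#' pure blue, 63 pure green, 4095 pure red.
#'
#' @param v Integer vector of values in 0..4095.
#' @return Integer matrix with columns `r`, `g`, `b` in 0..255.
#' @export
value_to_color <- function(v) {
  if (any(v < 0 | v > 4095)) stopf("value_to_color: values must lie in 0..4095")
  x <- log2(1 + v) / 12
  lo <- x <= 0.5
  r <- ifelse(lo, 0, round(255 * (2 * x - 1)))
  g <- ifelse(lo, round(255 * 2 * x), round(255 * (2 - 2 * x)))
  b <- ifelse(lo, round(255 * (1 - 2 * x)), 0)
  m <- cbind(r = as.integer(r), g = as.integer(g), b = as.integer(b))
  m
}

#' Render a spectrogram table to a PNG image
#'
#' Time runs along x, frequency along y (0 at the bottom, 100 kHz at the
#' top), with colours from [value_to_color()]. With `annotate = TRUE` the
#' image carries axes in seconds and kHz; with `annotate = FALSE` the raw
#' data raster is written one pixel per table cell, which pixel-level tests
#' rely on.
#'
#' @param tab A non-empty [spectrogram_table].
#' @param path Output PNG path.
#' @param annotate Draw axis annotations (default `TRUE`).
#' @param width,height Device size in pixels when annotating.
#' @return `path`, invisibly.
#' @export
render_spectrogram <- function(tab, path, annotate = TRUE,
                               width = 900, height = 480) {
  if (!inherits(tab, "spectrogram_table")) stopf("render_spectrogram: not a spectrogram_table")
  k <- nrow(tab$values)
  if (k == 0L) stopf("render_spectrogram: empty table")
  rgb01 <- value_to_color(as.integer(tab$values)) / 255
  # values: rows time, cols bin 0..255; image array: row 1 = top = bin 255
  arr <- array(0, dim = c(256L, k, 3L))
  for (ch in 1:3) {
    arr[, , ch] <- t(matrix(rgb01[, ch], nrow = k))[256:1, , drop = FALSE]
  }
  if (!annotate) {
    png::writePNG(arr, path)
    return(invisible(path))
  }
  grDevices::png(path, width = width, height = height,
                 type = if (capabilities("cairo")) "cairo" else "Xlib")
  op <- graphics::par(mar = c(4, 4, 1, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  t_span <- k * tab$dt
  graphics::plot(NA, xlim = c(0, t_span), ylim = c(0, 256 * tab$df / 1000),
                 xlab = "time (s)", ylab = "frequency (kHz)",
                 xaxs = "i", yaxs = "i")
  graphics::rasterImage(grDevices::as.raster(arr), 0, 0, t_span,
                        256 * tab$df / 1000, interpolate = FALSE)
  invisible(path)
}

#' Screen a spectrogram for ultrasonic calls
#'
#' Simple detector mirroring how calls are identified by eye on the live
#' display: the per-bin background is the median over time; cells inside the
#' 18-80 kHz band whose value exceeds the background by `snr_db` (in power
#' dB, `10 log10`) are candidates; runs of consecutive frames containing
#' candidates that last at least `min_dur` become call events.
#'
#' @param tab A [spectrogram_table] spanning at least 10 frames (needed for a
#'   meaningful background estimate).
#' @param snr_db Detection threshold above background in dB (default 10).
#' @param min_dur Minimum event duration in seconds (default 0.010).
#' @param band Screening band in Hz (default `c(18000, 80000)`).
#' @return A data.frame of events: `onset` (s, relative to the table origin),
#'   `duration` (s), `f_low`, `f_high` (Hz), `peak_snr` (dB).
#' @export
screen_calls <- function(tab, snr_db = 10, min_dur = 0.010,
                         band = c(18000, 80000)) {
  if (!inherits(tab, "spectrogram_table")) stopf("screen_calls: not a spectrogram_table")
  k <- nrow(tab$values)
  if (k < 10L) stopf("screen_calls: table spans %d frame(s); need at least 10 for background estimation", k)
  v <- tab$values
  bg <- apply(v, 2, stats::median)
  db <- 10 * log10(sweep(v + 1, 2, bg + 1, "/"))
  binfreq <- (seq_len(256) - 1) * tab$df
  inband <- binfreq >= band[1] & binfreq <= band[2]
  cand <- db >= snr_db
  cand[, !inband] <- FALSE
  active <- rowSums(cand) > 0
  min_frames <- max(1L, as.integer(ceiling(min_dur / tab$dt)))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= min_frames)
  out <- data.frame(onset = numeric(0), duration = numeric(0),
                    f_low = numeric(0), f_high = numeric(0),
                    peak_snr = numeric(0))
  t_rel <- as.numeric(tab$ts) - as.numeric(tab$origin)
  for (i in sel) {
    rows <- begins[i]:ends[i]
    cells <- which(cand[rows, , drop = FALSE], arr.ind = TRUE)
    fcols <- unique(cells[, 2])
    out[nrow(out) + 1L, ] <- c(t_rel[begins[i]],
                               r$lengths[i] * tab$dt,
                               min(binfreq[fcols]), max(binfreq[fcols]),
                               max(db[rows, inband]))
  }
  out
}
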