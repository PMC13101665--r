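origin_test <- as.POSIXct("2026-04-12 12:00:00", tz = "UTC")

test_that("CSV rows carry one ms timestamp plus 256 integers", {
  set.seed(41)
  tab <- spectrogram_table(matrix(sample(0:4095, 3 * 256, TRUE), nrow = 3),
                           origin = origin_test)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrogram_csv(tab, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  fields <- strsplit(lines, ",")
  expect_true(all(vapply(fields, length, integer(1)) == 257L))
  expect_match(fields[[1]][1], "^2026-04-12T12:00:00\\.000$")
  expect_match(fields[[3]][1], "\\.005$")  # 2 * 2.56 ms, ms precision
})

test_that("CSV write/read round-trips values and ms timestamps", {
  set.seed(43)
  tab <- spectrogram_table(matrix(sample(0:4095, 40 * 256, TRUE), nrow = 40),
                           origin = origin_test)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrogram_csv(tab, path)
  back <- read_spectrogram_csv(path)
  expect_identical(unname(back$values), unname(tab$values))
  expect_identical(round(as.numeric(back$ts) * 1000),
                   round(as.numeric(tab$ts) * 1000))
  # header flag round-trips too
  write_spectrogram_csv(tab, path, header = TRUE)
  expect_identical(unname(read_spectrogram_csv(path)$values),
                   unname(tab$values))
})

test_that("empty tables and malformed rows are handled gracefully", {
  tab0 <- spectrogram_table(matrix(integer(0), nrow = 0, ncol = 256),
                            origin = origin_test)
  path <- withr::local_tempfile(fileext = ".csv")
  expect_message(write_spectrogram_csv(tab0, path), "empty")
  expect_identical(readLines(path), character(0))
  # single valid row
  tab1 <- spectrogram_table(matrix(7L, nrow = 1, ncol = 256), origin = origin_test)
  write_spectrogram_csv(tab1, path)
  expect_equal(nrow(read_spectrogram_csv(path)$values), 1)
  # a row with 255 values is skipped and logged
  lines <- readLines(path)
  writeLines(c(lines, paste(c("2026-04-12T12:00:01.000", rep("1", 255)),
                            collapse = ",")), path)
  expect_message(back <- read_spectrogram_csv(path), "malformed")
  expect_equal(nrow(back$values), 1)
  # all rows malformed -> error
  writeLines(paste(rep("x", 10), collapse = ","), path)
  expect_error(suppressMessages(read_spectrogram_csv(path)), "no valid rows")
})

test_that("output filenames are timestamped before the extension", {
  t <- as.POSIXct("2026-04-12 12:00:00", tz = "UTC")
  expect_equal(timestamped_filename("a.csv", t), "a_20260412-120000.csv")
  # applying to an already-stamped name stacks a second stamp, not a mangled one
  once <- timestamped_filename("a.csv", t)
  expect_equal(timestamped_filename(once, t), "a_20260412-120000_20260412-120000.csv")
  expect_message(out <- timestamped_filename("b", t), "extension")
  expect_equal(out, "b_20260412-120000.csv")
  t2 <- t + 1
  expect_false(timestamped_filename("a.csv", t) == timestamped_filename("a.csv", t2))
})

test_that("colour mapping is the logarithmic blue-green-red gradient", {
  expect_equal(value_to_color(0L)[1, ], c(r = 0L, g = 0L, b = 255L))
  expect_equal(value_to_color(63L)[1, ], c(r = 0L, g = 255L, b = 0L))
  expect_equal(value_to_color(4095L)[1, ], c(r = 255L, g = 0L, b = 0L))
  expect_error(value_to_color(4096L), "0..4095")
  # monotone position along the gradient: index = (r - b) is non-decreasing
  v <- 0:4095
  m <- value_to_color(v)
  pos <- as.integer(m[, "r"]) - as.integer(m[, "b"])
  expect_true(all(diff(pos) >= 0))
})

test_that("rendering places a tone as a horizontal band at its bin row", {
  sp <- run_tone_chain(12000, duration = 0.06)
  tab <- spectrogram_table(t(sp$bins), origin = origin_test)
  path <- withr::local_tempfile(fileext = ".png")
  render_spectrogram(tab, path, annotate = FALSE)
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], c(256, nrow(tab$values)))
  # the reddest row should be bin 31, i.e. image row 256 - 31 = 225
  redness <- img[, , 1] - img[, , 3]
  expect_equal(which.max(rowMeans(redness)), 256 - 31)
  # annotated rendering also produces a PNG file
  path2 <- withr::local_tempfile(fileext = ".png")
  render_spectrogram(tab, path2, annotate = TRUE)
  expect_gt(file.info(path2)$size, 0)
})

test_that("blank frames render as solid blue columns", {
  vals <- matrix(0L, nrow = 4, ncol = 256)
  vals[c(1, 3), ] <- 1000L
  tab <- spectrogram_table(vals, origin = origin_test)
  path <- withr::local_tempfile(fileext = ".png")
  render_spectrogram(tab, path, annotate = FALSE)
  img <- png::readPNG(path)
  expect_true(all(img[, 2, 3] == 1) && all(img[, 2, 1] == 0)) # column 2 blue
  expect_true(all(img[, 4, 3] == 1))
  expect_error(render_spectrogram(
    spectrogram_table(matrix(integer(0), 0, 256)), path), "empty")
})

test_that("amplitude steps show up as colour changes along the band", {
  t <- (0:511) / 200000
  mk <- function(a) round(a * sin(2 * pi * 50000 * t))
  frames <- cbind(matrix(rep(mk(100), 5), ncol = 5),
                  matrix(rep(mk(1200), 5), ncol = 5))
  sp <- process_frames(frames)
  tab <- spectrogram_table(t(sp$bins), origin = origin_test)
  path <- withr::local_tempfile(fileext = ".png")
  render_spectrogram(tab, path, annotate = FALSE)
  img <- png::readPNG(path)
  row128 <- 256 - 128   # 50 kHz = bin 128
  expect_gt(img[row128, 8, 1], img[row128, 2, 1])  # redder after the step
})

test_that("call screening needs enough frames and gates the band", {
  short <- spectrogram_table(matrix(0L, nrow = 5, ncol = 256), origin = origin_test)
  expect_error(screen_calls(short), "at least 10")
  # loud 12 kHz tone (out of the 18-80 kHz band) must be ignored
  sp <- run_tone_chain(12000, duration = 0.06)
  tab <- spectrogram_table(t(sp$bins), origin = origin_test)
  expect_equal(nrow(screen_calls(tab)), 0)
})

test_that("pure noise rarely triggers the screen at a 10 dB threshold", {
  fails <- 0
  for (seed in 1:8) {
    ses <- gen_session(list(), noise_level = 0.02, duration = 0.2, seed = seed)
    cfgf <- frontend_config(board_gain = 10)
    v <- apply_frontend(mic_transduce(ses$wave, cfgf), cfgf)
    sp <- suppressMessages(process_frames(stream_to_frames(sample_and_quantize(v))))
    tab <- spectrogram_table(t(sp$bins), origin = origin_test)
    if (nrow(screen_calls(tab, snr_db = 10)) > 0) fails <- fails + 1
  }
  expect_lte(fails, 1)  # zero events expected in >= 95% of runs; allow one
})

test_that("an injected 50 kHz call at 20 dB SNR is recovered with ms accuracy", {
  level <- 0.1
  ses <- gen_session(list(call_spec("short50", onset = 0.15, level = level)),
                     noise_level = level / 10, duration = 0.4, seed = 77)
  cfgf <- frontend_config(board_gain = 10)
  v <- apply_frontend(mic_transduce(ses$wave, cfgf), cfgf)
  sp <- suppressMessages(process_frames(stream_to_frames(sample_and_quantize(v))))
  tab <- spectrogram_table(t(sp$bins), origin = origin_test)
  ev <- screen_calls(tab, snr_db = 10, min_dur = 0.010)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset - 0.15), 0.005)
  expect_true(ev$f_low >= 18000 && ev$f_high <= 80000)
  expect_true(ev$f_low <= 50000 && ev$f_high >= 50000)
  expect_gt(ev$peak_snr, 10)
})
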