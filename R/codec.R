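# Serial frame format: 256 x 12-bit bins packed into 512 bytes with
# start-of-frame (SoF) flag bits, plus a stream decoder with synchronization
# recovery, loss logging and blank-frame substitution. This codec is the
# on-wire contract of the whole chain, so it is implemented bit-exactly and
# property-tested for round-trip identity.
#
# Packing: each 12-bit bin becomes two bytes; the six most significant bits
# go in the low part of the first byte, the six least significant bits in the
# low part of the second. Bits 7 and 6 of every byte are reserved: both set in
# both bytes of the first pair of a frame (the SoF marker), clear everywhere
# else.

FRAME_BYTES <- 512L
SOF_MASK <- 192L  # bits 7 and 6

#' Encode one spectral frame for the serial link
#'
#' @param bins Integer vector of exactly 256 values in 0..4095.
#' @return A raw vector of exactly 512 bytes.
#' @examples
#' f <- encode_frame(rep(0L, 256))
#' f[1:2] # both 0xc0: the start-of-frame marker
#' @export
encode_frame <- function(bins) {
  if (length(bins) != 256L) stopf("encode_frame: need exactly 256 bins, got %d", length(bins))
  if (any(bins < 0 | bins > 4095) || any(bins != floor(bins))) {
    stopf("encode_frame: bins must be integers in 0..4095")
  }
  bytes <- integer(FRAME_BYTES)
  bytes[seq(1, FRAME_BYTES, 2)] <- bins %/% 64L
  bytes[seq(2, FRAME_BYTES, 2)] <- bins %% 64L
  bytes[1:2] <- bytes[1:2] + SOF_MASK
  as.raw(bytes)
}

#' Encode many spectral frames
#'
#' Vectorized equivalent of calling [encode_frame()] on every column and
#' concatenating the results.
#'
#' @param bins Integer matrix, 256 rows, one column per frame (e.g.
#'   `spectral_frames$bins`).
#' @return A raw vector of `512 * ncol(bins)` bytes.
#' @export
encode_frames <- function(bins) {
  if (inherits(bins, "spectral_frames")) bins <- bins$bins
  stopifnot(is.matrix(bins), nrow(bins) == 256L)
  if (any(bins < 0 | bins > 4095)) stopf("encode_frames: bins must lie in 0..4095")
  k <- ncol(bins)
  out <- matrix(0L, nrow = FRAME_BYTES, ncol = k)
  out[seq(1, FRAME_BYTES, 2), ] <- bins %/% 64L
  out[seq(2, FRAME_BYTES, 2), ] <- bins %% 64L
  out[1:2, ] <- out[1:2, ] + SOF_MASK
  as.raw(out)
}

# flagged-byte positions (bits 7&6 both set), computed chunk-wise so that
# multi-hundred-megabyte streams never materialize a full integer copy
flag_positions <- function(bytes, chunk = 2^26) {
  n <- length(bytes)
  pos <- vector("list", ceiling(n / chunk))
  off <- 0L
  i <- 1L
  while (off < n) {
    m <- min(chunk, n - off)
    iv <- as.integer(bytes[(off + 1L):(off + m)])
    pos[[i]] <- off + which(bitwAnd(iv, SOF_MASK) == SOF_MASK)
    off <- off + m
    i <- i + 1L
  }
  unlist(pos)
}

#' Decode a serial byte stream with synchronization recovery
#'
#' Scans for byte pairs whose flag bits (7 and 6) are set in both bytes — the
#' start-of-frame marker — and decodes 512-byte frames from each. Corruption
#' is data, not an exception: whenever the expected frame structure is absent
#' (a header appears early because bytes were lost, or the next frame does not
#' begin with a header), the decoder skips forward to the next header, logs
#' the gap, and substitutes zero-filled blank frames — one per missing
#' 512-byte slot, a partially transmitted frame counting as one — so the time
#' axis stays continuous. Frame timestamps advance by 2.56 ms per emitted
#' frame (decoded or blank).
#'
#' @param bytes Raw vector (possibly corrupted; possibly starting mid-frame).
#' @param t0 Time of the first frame, seconds.
#' @param keep_values If `FALSE`, only synchronization bookkeeping is done and
#'   no bin values are materialized — useful for loss audits of very long
#'   sessions.
#' @param frame_period Seconds per frame (default 512/200000 = 2.56 ms).
#' @return An object of class `decode_report`: `frames` (256 x n integer
#'   matrix, blanks zero-filled; `NULL` if `keep_values = FALSE`), `n_frames`
#'   (emitted frames including blanks), `good` (logical mask of decoded
#'   frames), `t` (frame start times), `losses` (data.frame with 0-based
#'   `byte_offset` and `bytes_skipped`, strictly increasing offsets),
#'   `blanks_inserted`.
#' @export
decode_stream <- function(bytes, t0 = 0, keep_values = TRUE,
                          frame_period = 512 / 200000) {
  n <- length(bytes)
  empty <- function() {
    structure(list(frames = if (keep_values) matrix(0L, 256, 0) else NULL,
                   n_frames = 0L, good = logical(0), t = numeric(0),
                   losses = data.frame(byte_offset = numeric(0),
                                       bytes_skipped = numeric(0)),
                   blanks_inserted = 0L),
              class = "decode_report")
  }
  if (n == 0L) return(empty())

  fpos <- flag_positions(bytes)
  # header candidates: flagged byte immediately followed by a flagged byte
  hdr <- if (length(fpos) >= 2L) fpos[which(diff(fpos) == 1L)] else integer(0)

  max_slots <- n %/% FRAME_BYTES + 2L
  starts <- integer(max_slots)       # byte position of each decoded frame
  slot_good <- logical(max_slots)    # good vs blank, in emission order
  ng <- 0L                           # decoded frames
  slots <- 0L                        # emitted frames (decoded + blank)
  loss_off <- numeric(0)
  loss_skip <- numeric(0)
  blanks <- 0L

  add_loss <- function(off0, skipped) {
    loss_off[length(loss_off) + 1L] <<- off0
    loss_skip[length(loss_skip) + 1L] <<- skipped
  }
  nh <- length(hdr)
  nf <- length(fpos)
  j <- 1L   # pointer into hdr
  fi <- 1L  # pointer into fpos
  cur <- 1L

  repeat {
    if (cur > n) break
    # locate the first header at or after cur
    while (j <= nh && hdr[j] < cur) j <- j + 1L
    if (j > nh) {                       # no more headers: unrecoverable tail
      add_loss(cur - 1L, n - cur + 1L)
      break
    }
    if (hdr[j] > cur) {                 # expected header absent: resync
      gap <- hdr[j] - cur
      add_loss(cur - 1L, gap)
      nb <- as.integer(ceiling(gap / FRAME_BYTES))
      blanks <- blanks + nb
      slots <- slots + nb
      cur <- hdr[j]
      next
    }
    # cur sits on a header
    if (cur + FRAME_BYTES - 1L > n) {   # incomplete trailing frame
      add_loss(cur - 1L, n - cur + 1L)
      break
    }
    # interior must be free of flagged bytes (positions cur+2 .. cur+511)
    while (fi <= nf && fpos[fi] <= cur + 1L) fi <- fi + 1L
    if (fi <= nf && fpos[fi] <= cur + FRAME_BYTES - 1L) {
      # a header arrived early: bytes of this frame were lost
      while (j <= nh && hdr[j] < cur + 2L) j <- j + 1L
      if (j > nh) {
        add_loss(cur - 1L, n - cur + 1L)
        break
      }
      gap <- hdr[j] - cur
      add_loss(cur - 1L, gap)
      nb <- as.integer(ceiling(gap / FRAME_BYTES))
      blanks <- blanks + nb
      slots <- slots + nb
      cur <- hdr[j]
      next
    }
    # clean frame
    ng <- ng + 1L
    slots <- slots + 1L
    starts[ng] <- cur
    slot_good[slots] <- TRUE
    cur <- cur + FRAME_BYTES
  }

  starts <- starts[seq_len(ng)]
  slot_good <- slot_good[seq_len(slots)]

  frames <- NULL
  if (keep_values) {
    frames <- matrix(0L, nrow = 256L, ncol = slots)
    if (ng > 0L) {
      good_cols <- which(slot_good)
      chunk <- 8192L
      for (c0 in seq(1L, ng, by = chunk)) {
        c1 <- min(c0 + chunk - 1L, ng)
        sc <- starts[c0:c1]
        idx <- rep(sc, each = FRAME_BYTES) + seq_len(FRAME_BYTES) - 1L
        m <- matrix(as.integer(bytes[idx]), nrow = FRAME_BYTES)
        hi <- bitwAnd(m[seq(1, FRAME_BYTES, 2), , drop = FALSE], 63L)
        lo <- bitwAnd(m[seq(2, FRAME_BYTES, 2), , drop = FALSE], 63L)
        frames[, good_cols[c0:c1]] <- hi * 64L + lo
      }
    }
  }
  if (length(loss_off) > 0L) {
    log_event("decoder", sprintf("%d loss event(s), %d byte(s) skipped, %d blank frame(s) inserted",
                                 length(loss_off), sum(loss_skip), blanks), "WARN")
  }
  structure(list(frames = frames, n_frames = slots, good = slot_good,
                 t = t0 + (seq_len(slots) - 1) * frame_period,
                 losses = data.frame(byte_offset = loss_off,
                                     bytes_skipped = loss_skip),
                 blanks_inserted = blanks),
            class = "decode_report")
}

#' @export
print.decode_report <- function(x, ...) {
  cat(sprintf("<decode_report> %d frame(s) (%d decoded, %d blank), %d loss event(s), %g byte(s) skipped\n",
              x$n_frames, sum(x$good), x$blanks_inserted,
              nrow(x$losses), sum(x$losses$bytes_skipped)))
  invisible(x)
}

#' UART throughput feasibility
#'
#' Required wire bit rate for the frame stream under 8N1 framing (start bit +
#' 8 data bits + stop bit = 10 bits per byte): `frame_bytes * 10 /
#' frame_period`. Feasible when that does not exceed the baud rate. At the
#' defaults: 512 bytes every 2.56 ms needs 2.0 Mbit/s against the 3 Mbaud
#' link.
#'
#' @param baud Link baud rate in Hz (default 3e6).
#' @param frame_bytes Bytes per frame (default 512).
#' @param frame_period Frame period in seconds (default 2.56 ms).
#' @return A list (class `uart_budget`) with `required_bps`, `baud`,
#'   `feasible`, `utilization`.
#' @export
uart_budget <- function(baud = 3e6, frame_bytes = 512, frame_period = 0.00256) {
  if (baud <= 0 || frame_bytes <= 0 || frame_period <= 0) {
    stopf("uart_budget: all inputs must be positive")
  }
  required <- frame_bytes * 10 / frame_period
  structure(list(required_bps = required, baud = baud,
                 feasible = required <= baud,
                 utilization = required / baud),
            class = "uart_budget")
}

#' @export
print.uart_budget <- function(x, ...) {
  cat(sprintf("<uart_budget> need %.3g Mbit/s of %.3g Mbaud (%.0f%%): %s\n",
              x$required_bps / 1e6, x$baud / 1e6, 100 * x$utilization,
              if (x$feasible) "feasible" else "NOT feasible"))
  invisible(x)
}

#' Inject independent byte deletions into a stream
#'
#' Fault-injection harness for decoder tests: each byte is dropped
#' independently with probability `prob`, emulating the rare byte losses of a
#' UART link without error correction. Draws from the current RNG stream.
#'
#' @param bytes Raw vector.
#' @param prob Per-byte deletion probability.
#' @return A list with `bytes` (the corrupted stream) and `dropped`
#'   (1-based positions deleted from the original stream).
#' @export
inject_byte_loss <- function(bytes, prob) {
  n <- length(bytes)
  k <- stats::rbinom(1, n, prob)
  if (k == 0L) return(list(bytes = bytes, dropped = integer(0)))
  dropped <- sort(sample.int(n, k))
  list(bytes = bytes[-dropped], dropped = dropped)
}
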