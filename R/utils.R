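# Shared numeric helpers. All fixed-point rounding in the digital pipeline goes
# through round_half_away() so the rounding convention is stated once.

#' Round half away from zero
#'
#' Rounding convention used at every fixed-point rounding site of the digital
#' pipeline (ADC code mapping, FFT component scaling). Unlike [base::round()],
#' ties are resolved away from zero, matching typical DSP hardware rounders.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values (still stored as doubles).
#' @examples
#' round_half_away(c(-1.5, -0.5, 0.5, 1.5)) # -2 -1 1 2
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured, stage-labelled log line. Everything the chain wants to surface
# (dropped remainders, decoder losses, malformed CSV rows) goes through here so
# tests can capture it with expect_message().
log_event <- function(stage, msg, level = "INFO") {
  message(sprintf("[%s] [%s] %s", level, stage, msg))
  invisible(NULL)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
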