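# Internal helpers: argument checking and classed errors so callers can
# distinguish configuration problems from degenerate data.

stop_corrtf <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "corrtf_error")))
}

config_error <- function(msg) stop_corrtf(msg, "corrtf_config_error")
argument_error <- function(msg) stop_corrtf(msg, "corrtf_argument_error")
degenerate_error <- function(msg) stop_corrtf(msg, "corrtf_degenerate_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' @noRd
check_band <- function(low_hz, high_hz, tr_seconds) {
  if (!is_scalar_number(low_hz) || !is_scalar_number(high_hz) ||
      !is_scalar_number(tr_seconds) || tr_seconds <= 0) {
    config_error("band edges and tr_seconds must be finite numbers, tr > 0")
  }
  nyquist <- 1 / (2 * tr_seconds)
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyquist)) {
    config_error(sprintf(
      "band must satisfy 0 < low (%g) < high (%g) < Nyquist (%g Hz)",
      low_hz, high_hz, nyquist))
  }
  invisible(nyquist)
}
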