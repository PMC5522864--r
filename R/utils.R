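# condition helpers: every package error carries "zygocall_error" plus a
# specific subclass so callers can branch on failure mode.

zc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "zygocall_error"), call = call))
}

stop_format     <- function(msg) zc_stop(msg, "zygocall_format_error")
stop_integrity  <- function(msg) zc_stop(msg, "zygocall_integrity_error")
stop_validation <- function(msg) zc_stop(msg, "zygocall_validation_error")
stop_degenerate <- function(msg) zc_stop(msg, "zygocall_degenerate_error")
stop_state      <- function(msg) zc_stop(msg, "zygocall_state_error")
stop_io         <- function(msg) zc_stop(msg, "zygocall_io_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# match a required header column case-insensitively; NA if absent
match_column <- function(header, name) {
  i <- match(tolower(name), tolower(header))
  if (is.na(i)) NA_integer_ else i
}

# full-precision numeric formatting so write/read round-trips are exact
format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    trimws(formatC(v, digits = 17, format = "g"))
  }, character(1))
}
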