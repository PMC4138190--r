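# Condition helpers: every error the package raises carries class
# "wga_error" plus a specific subclass so callers can branch on failure
# modes (invalid configuration, insufficient data, malformed records,
# fit failure) without string matching.

wga_stop <- function(msg, class, call. = sys.call(-1), ...) {
  stop(errorCondition(msg, ..., class = c(class, "wga_error"),
                      call = call.))
}

wga_stop_invalid <- function(msg, ...) {
  wga_stop(msg, "wga_invalid_config", call. = sys.call(-1), ...)
}

wga_stop_insufficient <- function(msg, ...) {
  wga_stop(msg, "wga_insufficient_data", call. = sys.call(-1), ...)
}

wga_stop_malformed <- function(msg, ...) {
  wga_stop(msg, "wga_malformed_input", call. = sys.call(-1), ...)
}
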