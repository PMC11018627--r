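# Classed conditions so callers (and the CLI) can map failures to exit codes:
#   missing input -> 2, parse/schema/validation/config -> 3, internal -> 4.

stop_kdparch <- function(msg, class) {
  stop(structure(
    class = c(class, "kdparch_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stop_parse      <- function(msg) stop_kdparch(msg, "kdparch_parse_error")
stop_schema     <- function(msg) stop_kdparch(msg, "kdparch_schema_error")
stop_validation <- function(msg) stop_kdparch(msg, "kdparch_validation_error")
stop_config     <- function(msg) stop_kdparch(msg, "kdparch_config_error")
stop_io         <- function(msg) stop_kdparch(msg, "kdparch_io_error")
stop_missing_input <- function(msg) stop_kdparch(msg, "kdparch_missing_input_error")
stop_internal   <- function(msg) stop_kdparch(msg, "kdparch_internal_error")
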