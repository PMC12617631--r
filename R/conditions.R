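# Typed error conditions so callers (and the CLI) can map failures to
# exit codes: validation/parse errors vs I/O errors.

fx_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fixiscan_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

fx_parse_error <- function(msg) fx_stop(msg, "fx_parse_error")
fx_validation_error <- function(msg) fx_stop(msg, "fx_validation_error")
fx_io_error <- function(msg) fx_stop(msg, "fx_io_error")
fx_contract_error <- function(msg) fx_stop(msg, "fx_contract_error")
fx_config_error <- function(msg) fx_stop(msg, "fx_config_error")
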