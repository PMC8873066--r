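# Structured conditions so callers (and the CLI) can distinguish bad input
# from bad files without string-matching messages.

abort_validation <- function(msg, ...) {
  stop(structure(
    class = c("tablesim_validation_error", "tablesim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

abort_parse <- function(msg, ...) {
  stop(structure(
    class = c("tablesim_parse_error", "tablesim_validation_error",
              "tablesim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

abort_io <- function(msg, ...) {
  stop(structure(
    class = c("tablesim_io_error", "tablesim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}
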