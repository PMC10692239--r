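# Classed conditions so callers (and the CLI) can distinguish failure modes.

domasm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("domasm_", class, "_error"), "domasm_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_validation <- function(msg, ...) domasm_stop("validation", msg, ...)
stop_geometry   <- function(msg, ...) domasm_stop("geometry", msg, ...)
stop_layout     <- function(msg, ...) domasm_stop("layout", msg, ...)
stop_format     <- function(msg, ...) domasm_stop("format", msg, ...)
stop_io         <- function(msg, ...) domasm_stop("io", msg, ...)
stop_degenerate <- function(msg, ...) domasm_stop("degenerate", msg, ...)
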