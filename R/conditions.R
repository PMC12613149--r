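# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes without string matching.

ts_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "timscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

invalid_input <- function(msg) ts_error("timscreen_invalid_input", msg)
config_error <- function(msg) ts_error("timscreen_config_error", msg)
io_error <- function(msg) ts_error("timscreen_io_error", msg)
data_error <- function(class, msg) ts_error(c(class, "timscreen_data_error"), msg)

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    invalid_input(sprintf("`%s` must be a single positive finite number", name))
}
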