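# Classed conditions so callers can trap specific failure modes
# (e.g. class "radflux_duplicate_location") instead of matching messages.

rf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("radflux_", class), "radflux_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

rf_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("radflux_", class), "radflux_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
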