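# Classed error conditions so callers (and tests) can dispatch on the kind
# of failure rather than on message text.
abort_riskmod <- function(message, class) {
  stop(structure(
    class = c(class, "riskmod_error", "error", "condition"),
    list(message = message, call = sys.call(-1L))
  ))
}
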