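#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can map failures to error
# categories: format/integrity/config problems are user-input errors,
# cannot-infer is a data condition (no usable negative-control split).
abort_restore <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(class, "restore_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1))
  ))
}

abort_format    <- function(msg) abort_restore(msg, "restore_format_error")
abort_integrity <- function(msg) abort_restore(msg, "restore_integrity_error")
abort_config    <- function(msg) abort_restore(msg, "restore_config_error")
abort_infer     <- function(msg) abort_restore(msg, "restore_infer_error")

# No-positive-cells: the two-group split for a (sample, reference, target)
# slice is unreliable (group means indistinguishable), so that slice cannot
# provide a background estimate.
abort_no_positive <- function(msg) {
  abort_restore(msg, c("restore_no_positive", "restore_infer_error"))
}
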