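# Classed conditions used across the package. Every error signalled by the
# API carries a subclass of "lims_error" so callers (and the CLI) can react
# to the error class rather than the message text.

lims_abort <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "lims_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

abort_not_found   <- function(msg, ...) lims_abort("lims_not_found_error", msg, ...)
abort_validation  <- function(msg, ...) lims_abort("lims_validation_error", msg, ...)
abort_duplicate   <- function(msg, ...) lims_abort("lims_duplicate_error", msg, ...)
abort_type        <- function(msg, ...) lims_abort("lims_type_error", msg, ...)
abort_permission  <- function(msg, ...) lims_abort("lims_permission_error", msg, ...)
abort_immutable   <- function(msg, ...) lims_abort("lims_immutable_error", msg, ...)
abort_capacity    <- function(msg, ...) lims_abort("lims_capacity_error", msg, ...)
abort_format      <- function(msg, ...) lims_abort("lims_format_error", msg, ...)
abort_integrity   <- function(msg, ...) lims_abort("lims_integrity_error", msg, ...)
abort_range       <- function(msg, ...) lims_abort("lims_range_error", msg, ...)
abort_alphabet    <- function(msg, ...) lims_abort("lims_alphabet_error", msg, ...)
abort_missing_seq <- function(msg, ...) lims_abort("lims_missing_sequence_error", msg, ...)
abort_version     <- function(msg, ...) lims_abort("lims_version_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
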