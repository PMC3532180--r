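# Classed conditions so callers (and the CLI) can distinguish failure modes.

kisaoStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "kisao_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

ioError      <- function(msg, ...) kisaoStop("kisao_io_error", msg, ...)
formatError  <- function(msg, ...) kisaoStop("kisao_format_error", msg, ...)
idError      <- function(msg, ...) kisaoStop("kisao_id_error", msg, ...)
unknownTermError <- function(msg, ...) kisaoStop("kisao_unknown_term_error", msg, ...)
branchError  <- function(msg, ...) kisaoStop("kisao_branch_error", msg, ...)
queryError   <- function(msg, ...) kisaoStop("kisao_query_error", msg, ...)
usageError   <- function(msg, ...) kisaoStop("kisao_usage_error", msg, ...)
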