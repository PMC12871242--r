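# Classed conditions so callers (and the command-line layer) can map
# failure kinds to exit codes without string matching.

cloniche_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cloniche_error", "error")))
}

abort_config     <- function(msg) cloniche_abort(msg, "cloniche_config_error")
abort_validation <- function(msg) cloniche_abort(msg, "cloniche_validation_error")
abort_domain     <- function(msg) cloniche_abort(msg, "cloniche_domain_error")
abort_io         <- function(msg) cloniche_abort(msg, "cloniche_io_error")
abort_generation <- function(msg) cloniche_abort(msg, "cloniche_generation_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
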