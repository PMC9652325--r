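# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes: config = 2, format = 3, numeric/degenerate = 4.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("hicomp_config_error", "hicomp_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("hicomp_format_error", "hicomp_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("hicomp_numeric_error", "hicomp_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
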