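# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so the command-line wrapper can map failures to
# exit codes (config error vs data error vs internal).
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = "skipticr_config_error"))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = "skipticr_data_error"))
}

vlog <- function(verbose, level, ...) {
  if (isTRUE(verbose >= level)) message(...)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
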