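# Classed error helpers so callers (and the CLI) can distinguish user/config
# mistakes from genuine bugs.

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("mpirecon_config_error", "mpirecon_error")))
}

abort_dim <- function(...) {
  stop(errorCondition(paste0(...), class = c("mpirecon_dimension_error", "mpirecon_error")))
}

abort_size <- function(...) {
  stop(errorCondition(paste0(...), class = c("mpirecon_size_error", "mpirecon_error")))
}

abort_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("mpirecon_numeric_error", "mpirecon_error")))
}
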