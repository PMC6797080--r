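# Classed conditions so callers can distinguish user error from model defects.

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("junctures_input_error", "error")))
}

stop_structural <- function(...) {
  stop(errorCondition(paste0(...), class = c("junctures_structural_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("junctures_numeric_error", "error")))
}

stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("junctures_contract_error", "error")))
}

stop_fit <- function(...) {
  stop(errorCondition(paste0(...), class = c("junctures_fit_error", "error")))
}

stop_identification <- function(...) {
  stop(errorCondition(paste0(...), class = c("junctures_identification_error", "error")))
}
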