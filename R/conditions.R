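# Structured error conditions. Every domain error carries a class so callers
# (and the CLI) can branch on it instead of matching message text.

ef_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "everflow_error")))
}

stop_panel_mismatch <- function(msg) ef_stop(msg, "ef_panel_mismatch")
stop_format          <- function(msg) ef_stop(msg, "ef_format_error")
stop_cap_exceeded    <- function(msg) ef_stop(msg, "ef_cap_exceeded")
stop_unknown_label   <- function(msg) ef_stop(msg, "ef_unknown_label")
stop_config          <- function(msg) ef_stop(msg, "ef_config_error")
stop_degenerate      <- function(msg) ef_stop(msg, "ef_degenerate_training")
stop_alignment       <- function(msg) ef_stop(msg, "ef_alignment_error")
stop_stratification  <- function(msg) ef_stop(msg, "ef_stratification_error")
stop_leakage         <- function(msg) ef_stop(msg, "ef_leakage_error")
stop_degenerate_counts <- function(msg) ef_stop(msg, "ef_degenerate_counts")
stop_dependency      <- function(msg) ef_stop(msg, "ef_dependency_error")
stop_io              <- function(msg) ef_stop(msg, "ef_io_error")
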