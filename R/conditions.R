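# Classed conditions so callers (and tests) can react to specific failure
# modes rather than matching message strings. Every error inherits "dg_error".

dg_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "dg_error"), ...)
}

dg_warn <- function(message, class = "dg_warning") {
  rlang::warn(message, class = class)
}

stop_dimension <- function(message, ...) dg_abort(message, "dg_dimension_error", ...)
stop_format    <- function(message, ...) dg_abort(message, "dg_format_error", ...)
stop_interval  <- function(message, ...) dg_abort(message, "dg_interval_error", ...)
stop_estimation<- function(message, ...) dg_abort(message, "dg_estimation_error", ...)
stop_margin    <- function(message, ...) dg_abort(message, "dg_margin_error", ...)
stop_degenerate<- function(message, ...) dg_abort(message, "dg_degenerate_error", ...)
stop_config    <- function(message, ...) dg_abort(message, "dg_config_error", ...)
stop_stability <- function(message, ...) dg_abort(message, c("dg_stability_error", "dg_config_error"), ...)
stop_validation<- function(message, ...) dg_abort(message, "dg_validation_error", ...)
stop_undefined_score <- function(message, ...) dg_abort(message, "dg_undefined_score_error", ...)
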