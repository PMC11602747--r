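#' @keywords internal
#' Structured errors: every user-facing failure carries a machine-readable
#' class so the pipeline (and its CLI wrapper) can map error families to
#' distinct exit codes.
sq_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "soilqi_error", "error")))
}

sq_schema_error     <- function(msg, ...) sq_abort(msg, "soilqi_schema_error", ...)
sq_validation_error <- function(msg, ...) sq_abort(msg, "soilqi_validation_error", ...)
sq_config_error     <- function(msg, ...) sq_abort(msg, "soilqi_config_error", ...)
sq_data_error       <- function(msg, ...) sq_abort(msg, "soilqi_data_error", ...)
sq_stage_error      <- function(msg, ...) sq_abort(msg, "soilqi_stage_error", ...)
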