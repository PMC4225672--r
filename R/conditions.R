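#' @importFrom rlang abort warn inform %||% .data
NULL

# All package errors are classed conditions so callers can branch on them.
# Every class is prefixed "trntopo_" and also carries the generic
# "trntopo_error" class.
trn_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("trntopo_", class), "trntopo_error"), ...)
}

trn_warn <- function(message, class = "warning") {
  rlang::warn(message, class = c(paste0("trntopo_", class), "trntopo_warning"))
}
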