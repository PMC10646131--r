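# Classed conditions so callers (and tests) can distinguish failure modes.
# All inherit from "kneetrack_error".

kt_condition <- function(subclass, message, call = sys.call(-1), data = list()) {
  structure(
    list(message = message, call = call, data = data),
    class = c(subclass, "kneetrack_error", "error", "condition")
  )
}

kt_parameter_error <- function(message, ...) {
  stop(kt_condition("kneetrack_parameter_error", message, data = list(...)))
}

kt_geometry_error <- function(message, ...) {
  stop(kt_condition("kneetrack_geometry_error", message, data = list(...)))
}

kt_convergence_error <- function(message, ...) {
  stop(kt_condition("kneetrack_convergence_error", message, data = list(...)))
}

kt_format_error <- function(message, ...) {
  stop(kt_condition("kneetrack_format_error", message, data = list(...)))
}

kt_contract_error <- function(message, ...) {
  stop(kt_condition("kneetrack_contract_error", message, data = list(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    kt_parameter_error(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    kt_parameter_error(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    kt_parameter_error(sprintf("'%s' must be >= 0 (got %g)", name, x))
  invisible(x)
}
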