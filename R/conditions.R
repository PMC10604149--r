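# Structured error conditions so callers (and tests) can distinguish
# bad parameters from bad data from numerical failure.

cf_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "cuttleflow_error", "error")))
}

abort_invalid_parameter <- function(msg, ...) {
  cf_abort(msg, "cuttleflow_invalid_parameter", ...)
}

abort_invalid_input <- function(msg, ...) {
  cf_abort(msg, "cuttleflow_invalid_input", ...)
}

abort_format_error <- function(msg, ...) {
  cf_abort(msg, "cuttleflow_format_error", ...)
}

abort_empty_input <- function(msg, ...) {
  cf_abort(msg, "cuttleflow_empty_input", ...)
}

abort_numerical_failure <- function(msg, ...) {
  cf_abort(msg, "cuttleflow_numerical_failure", ...)
}

abort_tracking_failure <- function(msg, ...) {
  cf_abort(msg, "cuttleflow_tracking_failure", ...)
}

# scalar finite numeric check used throughout the validators
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid_parameter(sprintf("`%s` must be a finite numeric scalar", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_invalid_parameter(sprintf(
      "`%s` = %g is outside its allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"))
  }
  invisible(x)
}
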