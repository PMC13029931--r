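# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish bad user input, out-of-domain values and malformed files.

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("anthroval_input_error", "anthroval_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("anthroval_domain_error", "anthroval_error")))
}

stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("anthroval_schema_error", "anthroval_error")))
}

# scalar positive / finite checks used across modules
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_input("'%s' must be finite and non-missing", name)
  }
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  if (bad || any(x > upper)) {
    stop_input("'%s' must lie in %s%g, %g]", name,
               if (strict_lower) "(" else "[", lower, upper)
  }
  invisible(x)
}
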