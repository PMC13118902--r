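# Shared condition classes and small validators.
#
# Validation failures signal a condition of class "rodaero_validation_error";
# solver non-convergence signals "rodaero_convergence_error". Both inherit
# from "error" so they stop() normally but can be caught selectively.

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("rodaero_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_convergence <- function(msg, ..., last = NA_real_, iterations = NA_integer_) {
  cond <- structure(
    class = c("rodaero_convergence_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1),
         last_iterate = last, iterations = iterations)
  )
  stop(cond)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_validation("`%s` must be a single positive finite number, got %s",
                    name, paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_validation("`%s` must be finite and non-negative", name)
  }
  invisible(x)
}

# Unit conversions are localized here: internal units are µm (length),
# µm³ (volume), g/cm³ (density), µg (mass).
UM3_PER_CM3 <- 1e12
MG_PER_G <- 1e3
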