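#' @keywords internal
"_PACKAGE"

## Argument checking helpers shared across the package. All throw
## classed conditions so callers/tests can distinguish validation
## failures from numerical ones.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dcvd_validation_error", "error")))
}

check_probability <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_invalid("`%s` must be a single numeric value", name)
  lo <- if (open) x > 0 else x >= 0
  hi <- if (open) x < 1 else x <= 1
  if (!lo || !hi)
    stop_invalid("`%s` must lie in %s0, 1%s, got %g", name,
                 if (open) "(" else "[", if (open) ")" else "]", x)
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid("`%s` must lie in [0, 1], got %g", name, x)
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || any(is.na(x)) || any(if (strict) x <= 0 else x < 0))
    stop_invalid("`%s` must be %s, got %s", name,
                 if (strict) "positive" else "non-negative",
                 paste(utils::head(x, 3), collapse = ", "))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_invalid("`%s` must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

## Deterministic child seeds: derive per-stage streams from one master
## seed so that independent stages do not share RNG state.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
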