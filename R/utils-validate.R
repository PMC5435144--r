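#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the pipeline driver) can distinguish
# bad input from numerical failure.
stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("screenval_validation_error", "screenval_error")))
}

stop_computation <- function(fmt, ..., payload = NULL) {
  cond <- errorCondition(sprintf(fmt, ...),
                         class = c("screenval_computation_error", "screenval_error"))
  if (!is.null(payload)) cond$payload <- payload
  stop(cond)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation("`%s` must be a single finite number", name)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_validation("`%s` = %g is outside the %s%g, %g%s range", name, x,
                    if (open_lower) "(" else "[", lower, upper,
                    if (open_upper) ")" else "]")
  invisible(x)
}

check_paired_vectors <- function(x, y, xname, yname, min_n = 1L) {
  if (!is.numeric(x) || !is.numeric(y))
    stop_validation("`%s` and `%s` must be numeric vectors", xname, yname)
  if (length(x) != length(y))
    stop_validation("`%s` (length %d) and `%s` (length %d) must have equal length",
                    xname, length(x), yname, length(y))
  if (length(x) < min_n)
    stop_validation("need at least %d paired observations, got %d", min_n, length(x))
  if (anyNA(x) || anyNA(y))
    stop_validation("`%s`/`%s` contain missing values", xname, yname)
  invisible(length(x))
}

# Deterministic sub-stream seeds derived from one master seed, so each
# random array (trait, items, criterion, ...) has its own stream and
# enlarging one array never perturbs another. Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 69069 + 12345 * k) %% 2147483629)
}

interpretation_band <- function(r) {
  # bands used for correlation-type coefficients in the report
  if (!is.finite(r)) return(NA_character_)
  a <- abs(r)
  if (a <= 0.40) "poor" else if (a <= 0.60) "moderate" else if (a <= 0.80) "good" else "excellent"
}
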