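# Classed conditions so callers can distinguish failure modes.

stop_gridrt <- function(class, msg, ..., data = NULL) {
  cond <- structure(
    class = c(class, "gridrt_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1), data = data)
  )
  stop(cond)
}

# Re-raise errors coming out of the C++ layer with a proper class.
rethrow_cpp <- function(expr) {
  tryCatch(
    expr,
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("^connectivity:", msg)) {
        stop_gridrt("gridrt_connectivity_error", "%s", msg)
      } else if (grepl("^runaway:", msg)) {
        stop_gridrt("gridrt_runaway_error", "%s", msg)
      }
      stop(e)
    }
  )
}

check_positive_int <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 1 ||
      abs(x - round(x)) > 1e-8) {
    stop_gridrt("gridrt_invalid_parameter",
                "`%s` must be a single positive integer (got %s)",
                name, paste(format(x), collapse = ", "))
  }
  as.integer(round(x))
}

check_number <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) ||
      x < lo || x > hi || (strict_lo && x <= lo)) {
    stop_gridrt("gridrt_invalid_parameter",
                "`%s` must be a number in %s%g, %g] (got %s)",
                name, if (strict_lo) "(" else "[", lo, hi,
                paste(format(x), collapse = ", "))
  }
  as.numeric(x)
}

check_seed <- function(seed) {
  if (length(seed) != 1 || !is.numeric(seed) || is.na(seed) ||
      abs(seed - round(seed)) > 1e-8 || seed < 0) {
    stop_gridrt("gridrt_invalid_parameter",
                "`seed` must be a single non-negative integer")
  }
  as.numeric(round(seed))
}
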