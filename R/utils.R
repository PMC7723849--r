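# Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero (commercial rounding), as used for printed
# percentages; base round() uses round-half-even.
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_low <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_low || x > upper) {
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
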