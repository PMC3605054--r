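# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  # keep derived seeds inside 32-bit integer range
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629L)
}

stop_tf <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_tf(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_tf(sprintf("'%s' = %g is outside its allowed range", name, x))
  invisible(x)
}

# Two-sided normal p-value together with an underflow-safe -log10(p).
normal_p2 <- function(z) {
  lp <- log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  list(p = max(exp(lp), 1e-300), neglog10 = -lp / log(10))
}

# Shared significance floor: p values below this are reported at the floor so
# downstream -log10 computations never see 0.
P_FLOOR <- 1e-300
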