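#' @keywords internal
"_PACKAGE"

# Classed condition helper so callers can distinguish domain errors,
# insufficient data, alignment problems etc. programmatically.
bm_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "burstmelt_error", "error", "condition"),
                      call = call))
}

bm_check_number <- function(x, name, lower = -Inf, upper = Inf,
                            strict_lower = FALSE, class = "domain_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    bm_error(sprintf("'%s' must be a single finite number", name), class)
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    bm_error(sprintf("'%s' = %g is outside its valid range %s%g, %g]",
                     name, x, if (strict_lower) "(" else "[", lower, upper), class)
  }
  invisible(x)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream;
# with seed = NULL the current stream is used (and advanced).
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Pseudo-inverse fallback for near-singular normal equations.
safe_solve <- function(A) {
  out <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(out)) {
    s <- svd(A)
    pos <- s$d > max(s$d) * 1e-12
    out <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  out
}
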