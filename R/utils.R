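
`%||%` <- function(a, b) if (is.null(a)) b else a

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE,
                          integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok_lo <- if (open_lower) x > lower else x >= lower
  ok_hi <- if (open_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("'%s' = %g is outside %s%g, %g%s", name, x,
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"), call. = FALSE)
  if (integer && abs(x - round(x)) > 1e-8)
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

# replicate-indexed RNG stream: deterministic and independent of the order in
# which replicates are evaluated (serial/parallel equivalence contract)
.replicate_seed <- function(base_seed, i) {
  (as.integer(base_seed) + 7919L * as.integer(i)) %% 2147483629L
}
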