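# internal argument checks shared across modules

check_number <- function(x, name, min = -Inf, max = Inf, allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x) ||
      any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric, got %s", name,
                  paste(utils::head(x, 3), collapse = ", ")))
  }
  if (any(x < min)) abort(sprintf("`%s` must be >= %g", name, min))
  if (any(x > max)) abort(sprintf("`%s` must be <= %g", name, max))
  invisible(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1) abort(sprintf("`%s` must be a single value", name))
  check_number(x, name, min = min, max = max)
}

# derive independent substream seeds from one user seed; kept < 2^31
substream_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483629L
}
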