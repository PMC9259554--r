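# Internal helpers shared across modules.

# round half away from zero, the convention used for all reported percentages
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# derive a child seed from a master seed; keeps results < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

# column names used for peak bins: "mz_<reference mass>"
bin_colnames <- function(bin_refs) sprintf("mz_%.4f", bin_refs)

is_binary_vector <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}
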