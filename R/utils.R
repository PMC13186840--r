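#' @importFrom rlang .data abort %||%
#' @importFrom stats rnorm runif fft optimize median pt qf pf qt sd var
#' @importFrom utils head tail
NULL

# Deterministic sub-seed derivation. Mixes a master seed with integer keys
# (condition index, replicate, subject, trial, ...) so every unit of work has
# its own reproducible stream, independent of how many other units run.
# All arithmetic stays below 2^53 so doubles are exact; result is in
# [1, 2^31 - 2], valid for set.seed().
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(seed %% m)
  for (k in as.double(c(...))) {
    s <- (s * 69069 + (k %% m) * 40692 + 12345) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

# Run code under a temporary seed without disturbing the caller's RNG state.
# seed = NULL means "use the current stream".
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

assert_scalar_prob <- function(x, name, lo = 0, hi = 1,
                               lo_open = TRUE, hi_open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (lo_open) x > lo else x >= lo
  hi_ok <- if (hi_open) x < hi else x <= hi
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%g, %g%s (got %g).",
      name, if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_series <- function(x, min_length = 8L, name = "x") {
  if (!is.numeric(x)) abort(sprintf("`%s` must be a numeric vector.", name))
  if (length(x) < min_length) {
    abort(sprintf(
      "`%s` must have at least %d observations (got %d).",
      name, min_length, length(x)
    ))
  }
  if (!all(is.finite(x))) abort(sprintf("`%s` contains non-finite values.", name))
  invisible(x)
}
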