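# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of well-separated child seeds from one master seed,
# kept inside the 32-bit integer range R requires.
derive_seeds <- function(seed, n) {
  (as.double(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647
}

# Two-sided normal p-value, floored away from exact zero so downstream
# validation (p in (0, 1]) is never tripped by underflow.
two_sided_p <- function(z) {
  pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- rlang::`%||%`
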