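# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# RNG state.  All user-facing stochastic operations route through this so
# that a `seed` argument is sufficient for bit-reproducibility.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a child seed, kept within the 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% 2147483629L) + 1L
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
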