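#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this so that library calls
# never clobber a user's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed derived from (seed, index); stays inside
# the 32-bit signed-integer range R requires of set.seed().
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
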