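# Seed handling. All stochastic operations take an explicit seed and run in a
# local RNG scope, so library calls never disturb the caller's RNG state and
# identical seeds give bit-identical results.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    check_number(seed, "seed")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage child seed from one root seed; keeps every stage
# reproducible in isolation. Stays below 2^31.
substream <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.double(seed) * 48271 + h * 2654435.0) %% 2147483629)
}
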