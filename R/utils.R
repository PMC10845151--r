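## Small internal helpers.

## Evaluate expr with a temporarily seeded RNG, restoring global RNG state.
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

## Derive a stream of child seeds from a master seed (kept below 2^31).
.childSeed <- function(seed, k) {
  (as.integer(seed) * 1103L + k * 12345L) %% 2147483647L
}
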