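# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# .Random.seed afterwards so package functions never perturb user RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

l2norm <- function(x) sqrt(sum(Mod(x)^2))

# Complex inner product <a, b> = sum(conj(a) * b)
cdot <- function(a, b) sum(Conj(a) * b)
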