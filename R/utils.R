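# Internal helpers: seeded evaluation and per-subject stream derivation.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive an independent child seed from a master seed and one or more stream
# indices (multiplicative mixing modulo the Mersenne prime 2^31 - 1, kept in
# 32-bit integer range).  Cohorts are extensible: subject i's stream does not
# depend on how many subjects follow it.
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- (as.numeric(master) %% m) + 1
  for (k in c(...)) {
    h <- (h + (as.numeric(k) + 1) * 2654435761) %% m
    # three LCG rounds decorrelate consecutive master seeds
    for (r in 1:3) h <- (h * 48271) %% m
  }
  for (r in 1:3) h <- (h * 48271) %% m
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
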