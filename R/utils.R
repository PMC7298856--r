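# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package take an explicit seed and route
# through this, so generators are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-stage seed derivation from one global seed. Keeps every
# derived seed a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, thin = 211L, split = 307L, area = 401L,
               filter = 503L, calibrate = 601L, final = 701L, mop = 809L,
               boot = 907L, proc = 1009L, cattle = 1103L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
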