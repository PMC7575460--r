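# Internal helpers shared across modules.

# Deterministic 32-bit seed mixing so that every sub-process (participant,
# trial, split) gets its own reproducible RNG stream derived from one master
# seed. Keeps results < 2^31 - 1 so they are valid R integer seeds.
mix_seed <- function(...) {
  parts <- vapply(list(...), as.numeric, numeric(1))
  x <- 104729
  for (p in parts) {
    x <- (x * 69069 + (p %% 2147483647) * 40503 + 12345) %% 2147483647
  }
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
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

# Total overlap (ms) of [onset, offset) intervals with window [w0, w1).
interval_overlap_total <- function(onset, offset, w0, w1) {
  if (length(onset) == 0) return(0)
  sum(pmax(0, pmin(offset, w1) - pmax(onset, w0)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
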