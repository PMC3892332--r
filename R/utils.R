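# Seed plumbing shared by all stochastic steps.
#
# Every user-facing function takes an explicit integer seed; internally the
# workflow derives per-(pseudo-absence set, repetition, algorithm) seeds from
# the master seed with a small counter-based hash so streams are independent
# and the whole design is reproducible from one integer.

#' Evaluate code under a seed, restoring the caller's RNG state
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Counter-based seed derivation: master seed plus up to three stream indices
# mapped into [1, 2^31 - 2].  Multipliers are distinct primes so different
# (pa_set, rep, alg) triples land on different streams.
derive_seed <- function(master, i = 0L, j = 0L, k = 0L) {
  m <- 2147483647  # 2^31 - 1
  x <- (as.numeric(master) %% m) * 48271 %% m
  x <- (x + as.numeric(i) * 2654435761 + as.numeric(j) * 40503 +
          as.numeric(k) * 2246822519) %% m
  as.integer(x %% (m - 1) + 1)
}
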