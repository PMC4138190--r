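# Seeding discipline: every stochastic operation takes an explicit
# `seed` argument and evaluates under `local_seed()`, which restores the
# caller's RNG state afterwards, so no package function mutates global
# randomness.  Compound simulations derive per-stage streams with
# `subseed()` (an LCG step over the Mersenne prime 2^31 - 1), giving a
# deterministic, collision-poor family of sub-seeds from one user seed.

local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    wga_stop_invalid("`seed` must be a single finite number or NULL")
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

subseed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647          # 2^31 - 1; products stay below 2^53
  s <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(2L)) {
    s <- (s * 48271 + as.numeric(k) * 104729 + 1) %% m
  }
  as.integer(s)
}
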