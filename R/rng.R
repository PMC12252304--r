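# Deterministic, state-isolated randomness.
#
# Every stochastic routine in the package takes an explicit integer seed and
# derives its draws inside `local_seed()`, which saves and restores the
# caller's RNG state, so package functions never perturb user RNG streams and
# identical (inputs, seed) always give identical outputs. Sub-streams are
# derived with a small integer hash so that e.g. per-image seeds never
# collide with per-epoch seeds.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# derive a sub-seed from a base seed and one or more stream indices
sub_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647)
  for (i in idx) {
    s <- (s * 69069 + as.double(i) * 104729 + 12345) %% 2147483647
  }
  as.integer(s)
}

local_runif <- function(n, min = 0, max = 1, seed) {
  local_seed(seed, stats::runif(n, min, max))
}

local_rnorm <- function(n, mean = 0, sd = 1, seed) {
  local_seed(seed, stats::rnorm(n, mean, sd))
}
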