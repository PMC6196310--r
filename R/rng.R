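# Self-contained RNG streams.  Package randomness never touches the caller's
# .Random.seed: each stream owns its state and restores the global state
# around every draw.

make_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed %% .Machine$integer.max)
  e$state <- NULL
  e
}

with_rng <- function(rng, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(rng$state)) set.seed(rng$seed)
  else assign(".Random.seed", rng$state, envir = globalenv())
  out <- force(code)
  rng$state <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  out
}

rng_sample <- function(rng, n, k) with_rng(rng, sample.int(n, k))
rng_int <- function(rng, n) with_rng(rng, sample.int(n, 1L))
rng_unif <- function(rng, k = 1L) with_rng(rng, stats::runif(k))
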