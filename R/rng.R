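# Seed handling: every randomized operation takes an optional integer seed.
# When a seed is given the global RNG state is saved, the RNG is seeded
# locally, and the previous state is restored on exit, so library calls never
# perturb user-level randomness.  When seed = NULL the current RNG stream is
# used (and advanced) as usual.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

rademacher <- function(n) {
  sample(c(-1, 1), n, replace = TRUE)
}
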