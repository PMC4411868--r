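## Internal helpers.

## Run `expr` under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a stream of child seeds from one master seed (kept < 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

## Map spike times to 1-based bin indices on a half-open grid
## [t0 + (k-1)*dt, t0 + k*dt). Times are treated at microsecond precision
## so boundary spikes land deterministically.
binIndex <- function(times, t0, dt, K) {
  us <- round((times - t0) * 1e6)
  wus <- dt * 1e6
  idx <- floor(us / wus) + 1
  pmin.int(pmax.int(idx, 1L), K)
}

## sum(lfactorial(y)) for count responses; constant part of the Poisson
## log-likelihood.
sumLfact <- function(y) sum(lfactorial(y))

`%||%` <- function(a, b) if (is.null(a)) b else a
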