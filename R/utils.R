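## Internal helpers shared across modules.

## Evaluate expr under a fixed RNG seed, restoring the caller's stream.
## All simulator entry points route their randomness through this: one
## explicitly seeded stream per call, no hidden global state.
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

## round-half-up to match printed-table style (82.5 -> 83); base round()
## rounds half to even.
.roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

.logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Shannon entropy in bits of a (possibly unnormalized) nonnegative vector.
.entropyBits <- function(p) {
  s <- sum(p)
  if (s <= 0) return(0)
  p <- p[p > 0] / s
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
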