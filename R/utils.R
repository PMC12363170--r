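## Internal helpers shared across modules.

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so no global state leaks.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

## Derive k reproducible child seeds (< 2^31) from one parent seed.
childSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)

isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}

starsForP <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
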