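## evaluate expr with a local RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## deterministic 31-bit seed derived from a base seed and integer keys
derive_seed <- function(base, ...) {
  keys <- c(base, ...)
  h <- 0
  for (k in keys) h <- (h * 7919 + (as.numeric(k) %% 104729) + 1) %% 2147483629
  as.integer(h) + 1L
}
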