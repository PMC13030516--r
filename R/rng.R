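# Seed hygiene: run expr under a fixed RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of distinct 31-bit sub-seeds from one master seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 + 1103515245 * as.numeric(k)) %%
               2147483647)
}
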