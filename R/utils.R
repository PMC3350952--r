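# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards; with seed = NULL the global stream is
# used (and advanced) as-is.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed (< 2^31) from a parent seed and an index,
# so per-element / per-stage streams are independent but fully determined.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 69621) %% 2147483587)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
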