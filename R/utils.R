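# internal helpers

# evaluate `expr` under a local RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
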