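# run `expr` under a local RNG state so seeded generators never disturb the
# caller's random stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically safe row-wise softmax
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# derive a stream of sub-seeds from one master seed, kept inside 32-bit range
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
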