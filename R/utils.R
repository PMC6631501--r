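# Run `expr` under `seed` without disturbing the caller's RNG stream.
# A NULL seed uses (and advances) the global stream.
with_seed_local <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Lower-triangle-free list of the k*(k-1)/2 ordered factor pairs, in the
# conventional order 12, 13, ..., 1k, 23, ..., (k-1)k.
factor_pairs <- function(k) {
  if (k < 2) return(matrix(integer(0), nrow = 2))
  utils::combn(k, 2)
}

# one-row tibble of coded settings named after the factors
actual_row <- function(factors, z) {
  tibble::as_tibble(stats::setNames(as.list(z), factors$name))
}
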