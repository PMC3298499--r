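## internal helpers shared across modules

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

## population (biased, divisor q) column standardisation of a vector
standardize_pop <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) {
    abort("cannot standardize a zero-variance vector.")
  }
  x / s
}

## deterministic sign convention: the entry of largest absolute value in each
## column is made positive (resolves SVD/ICA sign indeterminacy)
fix_signs <- function(m) {
  sgn <- apply(m, 2, function(x) {
    s <- sign(x[which.max(abs(x))])
    if (s == 0) 1 else s
  })
  sweep(m, 2, sgn, `*`)
}

check_count <- function(x, name, min = 1L, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min || x > max) {
    abort(sprintf("`%s` must be a whole number in [%s, %s].", name,
                  format(min), format(max)))
  }
  as.integer(x)
}
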