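## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards. All stochastic code in the package funnels
## through this so that a single integer seed determines every output.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a parent seed and a small index, staying inside
## 32-bit integer range. Distinct (seed, ...) tuples give distinct streams.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + 12345 + i) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Squared Euclidean distances between rows of x (n x m) and rows of y (q x m).
squaredDistances <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}
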