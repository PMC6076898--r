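#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the R random number generator seeded to `seed`, then
#' restores the previous global RNG state. All stochastic functions in this
#' package route their randomness through this helper so that no call leaves
#' a trace in the caller's RNG stream.
#'
#' @param seed A single finite integer-valued seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# round half away from zero (commercial rounding); base round() is
# round-half-to-even, which would not reproduce printed report cells
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# squared Euclidean cross-distances between rows of X and rows of Z
sqDistMatrix <- function(X, Z) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  d2
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                               strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("`%s` must be a single finite number in %s%s, %s%s", name,
                 if (strict) "(" else "[", lower, upper,
                 if (strict) ")" else "]"), call. = FALSE)
  invisible(x)
}
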