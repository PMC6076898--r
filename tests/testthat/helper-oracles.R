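# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (explicit loops, enumeration, quadrature) and share no
# code with the package implementation they check.

# brute-force minimum enclosing ball in 1-D or 2-D: the optimal ball is
# determined by some pair (diameter) or triple (circumcircle) of points
mebOracle <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  covers <- function(center, r2) {
    all(apply(X, 1L, function(p) sum((p - center)^2) <= r2 + 1e-9))
  }
  best <- list(center = X[1L, ], radius2 = Inf)
  consider <- function(center, r2) {
    if (r2 < best$radius2 && covers(center, r2))
      best <<- list(center = center, radius2 = r2)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    c2 <- (X[i, ] + X[j, ]) / 2
    consider(c2, sum((X[i, ] - c2)^2))
  }
  if (ncol(X) == 2L && n >= 3L) {
    for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L))
      for (k in (j + 1L):n) {
        A <- 2 * rbind(X[j, ] - X[i, ], X[k, ] - X[i, ])
        if (abs(det(A)) < 1e-12) next
        b <- c(sum(X[j, ]^2) - sum(X[i, ]^2), sum(X[k, ]^2) - sum(X[i, ]^2))
        cc <- drop(solve(A, b))
        consider(cc, sum((X[i, ] - cc)^2))
      }
  }
  best
}

# generic box/equality-constrained QP via kernlab::ipop:
#   max sum_i a_i K_ii - a' K a   s.t.  sum a = 1, 0 <= a <= C
qpDualOracle <- function(K, C) {
  n <- nrow(K)
  qp <- kernlab::ipop(c = -diag(K), H = 2 * K + 1e-10 * diag(n),
                      A = matrix(1, 1L, n), b = 1, l = rep(0, n),
                      u = rep(C, n), r = 0, sigf = 9)
  kernlab::primal(qp)
}

svddDualObjective <- function(K, alpha) {
  sum(alpha * diag(K)) - drop(t(alpha) %*% K %*% alpha)
}

# chi-square quantile by numerical inversion of the integrated density
chi2QuantileOracle <- function(d, p) {
  dens <- function(x) x^(d / 2 - 1) * exp(-x / 2) / (2^(d / 2) * gamma(d / 2))
  cdf <- function(q) stats::integrate(dens, 0, q, rel.tol = 1e-10)$value
  stats::uniroot(function(q) cdf(q) - p, c(1e-8, 200), tol = 1e-9)$root
}

# exhaustive maximin Kennard-Stone ranking with explicit loops
ksOracle <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  euc <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(NA, NA); bestD <- -1
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (euc(i, j) > bestD) { bestD <- euc(i, j); best <- c(i, j) }
  sel <- best
  while (length(sel) < n) {
    rest <- setdiff(seq_len(n), sel)
    dmin <- sapply(rest, function(r) min(sapply(sel, function(s) euc(r, s))))
    sel <- c(sel, rest[which.max(dmin)])
  }
  as.integer(sel)
}

# tiny SpectraSet fixture built in code
toySpectra <- function(n = 3L, p = 5L, seed = 42L) {
  withSeed(seed, SpectraSet(matrix(rnorm(n * p, 1, 0.3), n, p),
                            seq(8000, 5000, length.out = p),
                            rep(c("A", "B"), length.out = n)))
}
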