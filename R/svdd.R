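#' KernelSpec: kernel choice for SVDD
#'
#' The radial basis function kernel is used exactly in the form
#' `K(x, y) = exp(-||x - y||^2 / sigma^2)` — note the denominator is
#' `sigma^2`, not `2 sigma^2`; conventions differ between software packages
#' and the width grids used here assume this form. The linear kernel
#' `K(x, y) = <x, y>` yields the rigid minimum enclosing hypersphere.
#'
#' @slot kind `"rbf"` or `"linear"`.
#' @slot sigma kernel width (> 0, rbf only).
#' @export
setClass("KernelSpec", slots = c(kind = "character", sigma = "numeric"))

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("rbf", "linear"))
    msg <- c(msg, "kind must be 'rbf' or 'linear'")
  if (object@kind == "rbf" &&
      (length(object@sigma) != 1L || !is.finite(object@sigma) ||
       object@sigma <= 0))
    msg <- c(msg, "sigma must be a single positive number for the rbf kernel")
  if (length(msg)) msg else TRUE
})

#' @param kind,sigma see slots.
#' @rdname KernelSpec-class
#' @export
kernelSpec <- function(kind = c("rbf", "linear"), sigma = NA_real_) {
  kind <- match.arg(kind)
  new("KernelSpec", kind = kind, sigma = as.numeric(sigma))
}

#' Radial basis function kernel between two vectors
#'
#' `exp(-||a - b||^2 / sigma^2)`, in `(0, 1]`.
#'
#' @param a,b numeric vectors of equal length.
#' @param sigma kernel width (> 0).
#' @return Kernel similarity (scalar).
#' @examples
#' rbfKernel(c(0, 0), c(1, 0), 1)  # exp(-1)
#' @export
rbfKernel <- function(a, b, sigma) {
  if (length(a) != length(b))
    stop("`a` and `b` must have equal length", call. = FALSE)
  assertScalarNumber(sigma, "sigma", lower = 0, strict = TRUE)
  exp(-sum((a - b)^2) / sigma^2)
}

# kernel Gram / cross matrix between rows of X and rows of Z
kernelMatrix <- function(X, Z, kernel) {
  switch(kernel@kind,
         rbf = exp(-sqDistMatrix(X, Z) / kernel@sigma^2),
         linear = tcrossprod(as.matrix(X), as.matrix(Z)))
}

# Solve the SVDD dual
#   max  sum_i alpha_i K_ii - alpha' K alpha
#   s.t. sum alpha = 1, 0 <= alpha_i <= C
# by pairwise coordinate ascent (SMO-style): repeatedly pick the pair with
# the largest KKT violation (max gradient among increasable vs min gradient
# among decreasable coordinates) and solve the 1-D subproblem analytically.
svddSolveDual <- function(K, C, tol = 1e-10, maxIter = 1e5) {
  n <- nrow(K)
  if (n == 1L) return(1)
  alpha <- rep(1 / n, n)
  dK <- diag(K)
  Ka <- as.vector(K %*% alpha)
  eps <- C * 1e-12
  for (it in seq_len(maxIter)) {
    g <- dK - 2 * Ka
    up <- which(alpha < C - eps)
    dn <- which(alpha > eps)
    i <- up[which.max(g[up])]
    j <- dn[which.min(g[dn])]
    viol <- g[i] - g[j]
    if (viol < tol) break
    eta <- dK[i] - 2 * K[i, j] + dK[j]
    step <- if (eta > 1e-15) viol / (2 * eta) else Inf
    step <- min(step, C - alpha[i], alpha[j])
    alpha[i] <- alpha[i] + step
    alpha[j] <- alpha[j] - step
    Ka <- Ka + step * (K[, i] - K[, j])
  }
  alpha
}

#' SVDDModel: fitted support vector data description
#'
#' The minimum-volume hypersphere (in kernel feature space) around the
#' target class. Training points with Lagrange multiplier `alpha > 0` are
#' support vectors; unbounded ones (`0 < alpha < C`) lie exactly on the
#' sphere and bounded ones (`alpha = C`) outside it.
#'
#' @slot supportVectors support-vector coordinates (rows).
#' @slot alphas their Lagrange multipliers; `sum(alphas) = 1`,
#'   `0 <= alpha <= C`.
#' @slot kernel the [KernelSpec-class] used.
#' @slot C box constraint `1 / (n * f)` from the rejection fraction `f`.
#' @slot radius2 squared sphere radius, mean squared center distance over
#'   unbounded support vectors.
#' @slot offset cached `alpha' K alpha` term of the center-distance
#'   expansion.
#' @slot info diagnostic list (n, f, SV counts, training rejections).
#' @export
setClass("SVDDModel",
  slots = c(supportVectors = "matrix", alphas = "numeric",
            kernel = "KernelSpec", C = "numeric", radius2 = "numeric",
            offset = "numeric", info = "list"))

setValidity("SVDDModel", function(object) {
  msg <- character()
  if (length(object@alphas) != nrow(object@supportVectors))
    msg <- c(msg, "one alpha per support vector required")
  if (abs(sum(object@alphas) - 1) > 1e-8)
    msg <- c(msg, "alphas must sum to 1")
  if (any(object@alphas < 0 | object@alphas > object@C + 1e-12))
    msg <- c(msg, "alphas must lie in [0, C]")
  if (object@radius2 < 0) msg <- c(msg, "radius2 must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SVDDModel", function(object) {
  cat(sprintf(
    "SVDDModel: %d SVs (%d on boundary, %d outside) of n=%d, %s kernel%s, R^2=%.4g\n",
    nrow(object@supportVectors), object@info$nUnbounded,
    object@info$nBounded, object@info$n, object@kernel@kind,
    if (object@kernel@kind == "rbf")
      sprintf(" (sigma=%.4g)", object@kernel@sigma) else "",
    object@radius2))
  invisible(object)
})

#' Fit a support vector data description
#'
#' Solves the SVDD dual (maximize `sum alpha_i K_ii - alpha' K alpha`
#' subject to `sum alpha = 1`, `0 <= alpha_i <= C`) for the minimum
#' enclosing hypersphere in kernel feature space. The penalty is
#' parameterized through the target rejection fraction `f` via
#' `C = 1 / (n * f)`, so at most about `f * n` training samples fall
#' outside the sphere. The squared radius is the mean squared
#' center-distance over unbounded support vectors; if every support vector
#' is at the box bound the maximum squared distance among them is used and
#' a warning is emitted.
#'
#' @param X training matrix (target class only), samples in rows.
#' @param kernel A [KernelSpec-class] (default rbf with `sigma = 1`).
#' @param f rejection fraction in (0, 1), default 0.1.
#' @param tol KKT stopping tolerance for the dual solver; kept well below
#'   the 1e-9 acceptance guard so that boundary support vectors classify
#'   consistently.
#' @return An [SVDDModel-class].
#' @examples
#' m <- svddFit(matrix(c(0, 1, 2), 3), kernelSpec("linear"), f = 0.1)
#' svddDistance2(m, 5)  # 16: center is at 1
#' @export
svddFit <- function(X, kernel = kernelSpec("rbf", 1), f = 0.1,
                    tol = 1e-10) {
  X <- if (is.null(dim(X))) matrix(X, ncol = 1L) else as.matrix(X)
  stopifnot(is(kernel, "KernelSpec"))
  methods::validObject(kernel)
  assertScalarNumber(f, "f", lower = 0, upper = 1, strict = TRUE)
  n <- nrow(X)
  if (n < 1L) stop("at least one training sample required", call. = FALSE)
  C <- 1 / (n * f)
  K <- kernelMatrix(X, X, kernel)
  alpha <- svddSolveDual(K, C, tol = tol)
  # float-safe support vector classification
  isZero <- alpha < 1e-10 * C
  isBounded <- alpha > C * (1 - 1e-8)
  offset <- drop(crossprod(alpha, K %*% alpha))
  d2 <- diag(K) - 2 * as.vector(K %*% alpha) + offset
  unb <- !isZero & !isBounded
  if (any(unb)) {
    radius2 <- mean(d2[unb])
  } else {
    warning("no unbounded support vector; using max squared SV distance as radius2")
    radius2 <- max(d2[!isZero])
  }
  radius2 <- max(radius2, 0)
  sv <- !isZero
  new(Class = "SVDDModel", supportVectors = X[sv, , drop = FALSE],
      alphas = alpha[sv] / sum(alpha[sv]), kernel = kernel, C = C,
      radius2 = radius2, offset = offset,
      info = list(n = n, f = f, nBounded = sum(isBounded),
                  nUnbounded = sum(unb),
                  nTrainRejected = sum(d2 > radius2 + 1e-9)))
}

#' Squared distance to the SVDD center
#'
#' `K(z, z) - 2 sum_i alpha_i K(x_i, z) + offset` in kernel feature space;
#' for training points this reproduces the fit-time geometry.
#'
#' @param model An [SVDDModel-class].
#' @param Z matrix of points (rows) or a single vector.
#' @return Numeric vector of squared center distances.
#' @export
svddDistance2 <- function(model, Z) {
  stopifnot(is(model, "SVDDModel"))
  Z <- if (is.null(dim(Z))) matrix(Z, ncol = ncol(model@supportVectors))
       else as.matrix(Z)
  if (ncol(Z) != ncol(model@supportVectors))
    stop("dimension mismatch with the fitted feature space", call. = FALSE)
  Kzz <- switch(model@kernel@kind, rbf = rep(1, nrow(Z)),
                linear = rowSums(Z^2))
  Kxz <- kernelMatrix(model@supportVectors, Z, model@kernel)
  Kzz - 2 * as.vector(crossprod(Kxz, model@alphas)) + model@offset
}

#' Accept/reject test points under an SVDD
#'
#' A point is accepted (classified as target) when its squared center
#' distance does not exceed the squared radius; boundary points are
#' accepted.
#'
#' @param model An [SVDDModel-class].
#' @param Z matrix of points (rows) or a single vector.
#' @return Logical vector, `TRUE` = accepted as target.
#' @export
svddPredict <- function(model, Z) {
  svddDistance2(model, Z) <= model@radius2 + 1e-9
}
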