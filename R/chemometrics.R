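#' PCAModel: mean-centered principal component model
#'
#' @slot mean column means of the training matrix (original-variable space).
#' @slot loadings `n_points x n_components` matrix with orthonormal columns;
#'   each column is oriented so its largest-magnitude entry is positive.
#' @slot explainedVarianceRatio fraction of total variance per retained
#'   component, non-increasing.
#' @export
setClass("PCAModel",
  slots = c(mean = "numeric", loadings = "matrix",
            explainedVarianceRatio = "numeric"))

setValidity("PCAModel", function(object) {
  msg <- character()
  L <- object@loadings
  if (nrow(L) != length(object@mean))
    msg <- c(msg, "nrow(loadings) must equal length(mean)")
  if (ncol(L) != length(object@explainedVarianceRatio))
    msg <- c(msg, "one variance ratio per loading column required")
  g <- crossprod(L)
  if (max(abs(g - diag(ncol(L)))) > 1e-8)
    msg <- c(msg, "loading columns must be orthonormal")
  r <- object@explainedVarianceRatio
  if (any(r < 0 | r > 1) || is.unsorted(rev(r)) || sum(r) > 1 + 1e-12)
    msg <- c(msg, "variance ratios must be non-increasing fractions summing to <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d variables -> %d components (%s%% of variance)\n",
              nrow(object@loadings), ncol(object@loadings),
              paste(sprintf("%.1f", 100 * object@explainedVarianceRatio),
                    collapse = " + ")))
  invisible(object)
})

#' Fit a mean-centered PCA
#'
#' Principal components of the column-mean-centered data matrix, computed by
#' singular value decomposition. Variance ratios are singular-value energies
#' relative to the total variance of the centered matrix. For
#' reproducibility across platforms each loading column is sign-fixed so
#' that its largest-magnitude entry is positive.
#'
#' @param X numeric matrix, samples in rows (`n >= 2`).
#' @param nComponents number of components to keep,
#'   `<= min(n - 1, ncol(X))`.
#' @return A [PCAModel-class].
#' @export
pcaFit <- function(X, nComponents) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  kmax <- min(n - 1L, p)
  if (!is.numeric(nComponents) || nComponents < 1 || nComponents > kmax)
    stop(sprintf("nComponents must be in 1..%d", kmax), call. = FALSE)
  k <- as.integer(nComponents)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = kmax)
  total <- sum(sv$d^2)
  ratio <- if (total > 0) sv$d[seq_len(k)]^2 / total else rep(0, k)
  L <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  new("PCAModel", mean = mu, loadings = L,
      explainedVarianceRatio = ratio)
}

#' Project data onto a fitted PCA
#'
#' Scores are `(X - mean) %*% loadings`, always using the fit-time mean and
#' loadings (no refit on new data).
#'
#' @param model A [PCAModel-class].
#' @param X matrix (or single row) with `ncol(X) == length(model@mean)`.
#' @return Score matrix, `nrow(X) x n_components`.
#' @export
pcaTransform <- function(model, X) {
  stopifnot(is(model, "PCAModel"))
  X <- if (is.null(dim(X))) matrix(X, 1L) else as.matrix(X)
  if (ncol(X) != length(model@mean))
    stop("column count does not match the fitted variable space", call. = FALSE)
  sweep(X, 2L, model@mean) %*% model@loadings
}

#' Reconstruct data from PCA scores
#'
#' @param model A [PCAModel-class].
#' @param scores score matrix.
#' @return Matrix in the original variable space.
#' @export
pcaReconstruct <- function(model, scores) {
  stopifnot(is(model, "PCAModel"))
  scores <- as.matrix(scores)
  sweep(scores %*% t(model@loadings), 2L, model@mean, "+")
}

#' Kennard-Stone representative ranking
#'
#' Deterministic maximin ranking of samples: the first two selections are
#' the pair with the largest Euclidean distance; each subsequent selection
#' maximizes the minimum distance to all previously selected samples. Ties
#' are broken toward the lowest sample index, and the initial pair is
#' ordered ascending. Earlier positions in the returned order are the more
#' representative samples.
#'
#' @param X numeric matrix, samples in rows (`n >= 2`).
#' @return Integer permutation of `1:nrow(X)`, most representative first.
#' @examples
#' kennardStoneRank(matrix(c(0, 1, 10), 3))  # 1 3 2
#' @export
kennardStoneRank <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("Kennard-Stone ranking requires >= 2 samples",
                   call. = FALSE)
  D <- sqrt(sqDistMatrix(X, X))
  mx <- max(D)
  hit <- which(D == mx, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  order <- c(hit[1, 1], hit[1, 2])
  remaining <- setdiff(seq_len(n), order)
  minD <- pmin(D[, order[1]], D[, order[2]])
  while (length(remaining)) {
    best <- remaining[which.max(minD[remaining])]
    order <- c(order, best)
    remaining <- setdiff(remaining, best)
    minD <- pmin(minD, D[, best])
  }
  as.integer(order)
}
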