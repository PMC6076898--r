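#' KNNDDModel: k-nearest-neighbour data description
#'
#' Accepts a test point when its local density is at least that of its
#' nearest training neighbour, operationalized as a distance ratio: the
#' distance from the test point to its k-th training neighbour divided by
#' the distance from that neighbour to its own k-th neighbour (the
#' neighbour's search excludes itself).
#'
#' @slot training stored training matrix (rows = samples).
#' @slot k neighbour count, `1 <= k < n_training`.
#' @slot threshold acceptance bound on the distance ratio (> 0; 1 gives the
#'   plain density comparison).
#' @export
setClass("KNNDDModel",
  slots = c(training = "matrix", k = "integer", threshold = "numeric"))

setValidity("KNNDDModel", function(object) {
  msg <- character()
  if (object@k < 1L || object@k >= nrow(object@training))
    msg <- c(msg, "k must satisfy 1 <= k < n_training")
  if (length(object@threshold) != 1L || object@threshold <= 0)
    msg <- c(msg, "threshold must be a single value > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KNNDDModel", function(object) {
  cat(sprintf("KNNDDModel: n=%d training points, k=%d, threshold=%.3g\n",
              nrow(object@training), object@k, object@threshold))
  invisible(object)
})

#' Fit a k-nearest-neighbour data description
#'
#' @param X training matrix (target class only), samples in rows.
#' @param k neighbour count (default 1, the first nearest neighbour).
#' @param threshold acceptance bound on the distance ratio (default 1).
#' @return A [KNNDDModel-class].
#' @export
knnddFit <- function(X, k = 1L, threshold = 1) {
  X <- if (is.null(dim(X))) matrix(X, ncol = 1L) else as.matrix(X)
  new("KNNDDModel", training = X, k = as.integer(k),
      threshold = as.numeric(threshold))
}

# distance to the k-th smallest entry and its index
kthNN <- function(dists, k) {
  ord <- order(dists)
  idx <- ord[k]
  list(dist = dists[idx], index = idx)
}

#' KNNDD novelty score
#'
#' `||z - NN_k(z)|| / ||NN_k(z) - NN_k(NN_k(z))||`, with the convention
#' `0/0 = 0` (accept: the point duplicates a duplicated training sample)
#' and `x/0 = Inf` for `x > 0` (reject).
#'
#' @param model A [KNNDDModel-class].
#' @param Z matrix of points (rows) or a single vector.
#' @return Numeric vector of ratio scores (lower = more target-like).
#' @export
knnddScore <- function(model, Z) {
  stopifnot(is(model, "KNNDDModel"))
  Tr <- model@training
  Z <- if (is.null(dim(Z))) matrix(Z, ncol = ncol(Tr)) else as.matrix(Z)
  if (ncol(Z) != ncol(Tr))
    stop("dimension mismatch with the training space", call. = FALSE)
  k <- model@k
  Dzt <- sqrt(sqDistMatrix(Z, Tr))
  Dtt <- sqrt(sqDistMatrix(Tr, Tr))
  diag(Dtt) <- Inf  # a training point's own neighbour search excludes itself
  vapply(seq_len(nrow(Z)), function(i) {
    nn <- kthNN(Dzt[i, ], k)
    den <- kthNN(Dtt[nn$index, ], k)$dist
    if (nn$dist == 0) 0
    else if (den == 0) Inf
    else nn$dist / den
  }, numeric(1))
}

#' Accept/reject test points under a KNNDD
#'
#' @param model A [KNNDDModel-class].
#' @param Z matrix of points (rows) or a single vector.
#' @return Logical vector, `TRUE` = accepted (score `<= threshold`).
#' @examples
#' m <- knnddFit(rbind(c(0, 0), c(1, 0)), k = 1)
#' knnddPredict(m, c(0.4, 0))  # TRUE (score 0.4)
#' knnddPredict(m, c(3, 0))    # FALSE (score 2)
#' @export
knnddPredict <- function(model, Z) {
  knnddScore(model, Z) <= model@threshold
}
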