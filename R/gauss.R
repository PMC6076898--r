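#' Chi-square quantile threshold for Mahalanobis acceptance
#'
#' The squared Mahalanobis distance of a d-dimensional Gaussian vector is
#' chi-square distributed with d degrees of freedom, so accepting a
#' `coverage` fraction of target objects requires the threshold
#' `theta = qchisq(coverage, d)`.
#'
#' @param d degrees of freedom (>= 1).
#' @param coverage target acceptance fraction in (0, 1).
#' @return The chi-square quantile (scalar).
#' @examples
#' chi2Quantile(2, 0.95)  # 5.9915
#' @export
chi2Quantile <- function(d, coverage) {
  if (!is.numeric(d) || length(d) != 1L || d < 1)
    stop("`d` must be a single value >= 1", call. = FALSE)
  assertScalarNumber(coverage, "coverage", lower = 0, upper = 1,
                     strict = TRUE)
  stats::qchisq(coverage, df = d)
}

#' GaussModel: Gaussian density data description
#'
#' A unimodal Gaussian fitted to the target class; a point is accepted when
#' its squared Mahalanobis distance to the mean falls below the chi-square
#' quantile at the chosen coverage. The covariance is regularized as
#' `Sigma' = Sigma + lambda I` (or replaced by a pseudoinverse) to handle
#' badly scaled or rank-deficient data.
#'
#' @slot mu mean vector.
#' @slot sigmaReg regularized covariance `Sigma + lambda I` (symmetric).
#' @slot precision its inverse (or pseudoinverse).
#' @slot lambda diagonal regularization used.
#' @slot invMode `"regularized"` (direct inverse) or `"pseudoinverse"`.
#' @slot theta squared-Mahalanobis acceptance threshold
#'   `chi2Quantile(d, coverage)`.
#' @slot coverage target acceptance fraction.
#' @slot d data dimension.
#' @export
setClass("GaussModel",
  slots = c(mu = "numeric", sigmaReg = "matrix", precision = "matrix",
            lambda = "numeric", invMode = "character", theta = "numeric",
            coverage = "numeric", d = "integer"))

setValidity("GaussModel", function(object) {
  msg <- character()
  if (max(abs(object@sigmaReg - t(object@sigmaReg))) > 1e-8)
    msg <- c(msg, "sigmaReg must be symmetric")
  if (object@theta <= 0) msg <- c(msg, "theta must be > 0")
  want <- chi2Quantile(object@d, object@coverage)
  if (abs(object@theta - want) > 1e-8)
    msg <- c(msg, "theta must equal the chi-square quantile at the coverage")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GaussModel", function(object) {
  cat(sprintf(
    "GaussModel: d=%d, coverage=%.3g (theta=%.4g), lambda=%.3g, %s inverse\n",
    object@d, object@coverage, object@theta, object@lambda, object@invMode))
  invisible(object)
})

#' Fit a Gaussian data description
#'
#' `mu` is the sample mean and `Sigma` the sample covariance (divisor
#' `n - 1`). The default regularization is scale-aware,
#' `lambda = 1e-6 * trace(Sigma) / d`. In `"regularized"` mode
#' `Sigma + lambda I` is inverted directly and a near-singular matrix is an
#' error; in `"pseudoinverse"` mode the Moore-Penrose pseudoinverse is used
#' and rank-deficient data yield finite scores.
#'
#' @param X training matrix (target class only), samples in rows;
#'   `n >= d + 1` recommended.
#' @param lambda diagonal regularization (>= 0); `NULL` for the scale-aware
#'   default.
#' @param coverage target acceptance fraction (default 0.95).
#' @param invMode `"regularized"` or `"pseudoinverse"`.
#' @return A [GaussModel-class].
#' @export
gaussFit <- function(X, lambda = NULL, coverage = 0.95,
                     invMode = c("regularized", "pseudoinverse")) {
  X <- if (is.null(dim(X))) matrix(X, ncol = 1L) else as.matrix(X)
  invMode <- match.arg(invMode)
  d <- ncol(X)
  if (nrow(X) < 2L) stop("at least 2 samples required", call. = FALSE)
  mu <- colMeans(X)
  Sigma <- stats::cov(X)
  if (is.null(lambda)) lambda <- 1e-6 * sum(diag(Sigma)) / d
  assertScalarNumber(lambda, "lambda", lower = 0)
  sigmaReg <- Sigma + lambda * diag(d)
  sigmaReg <- (sigmaReg + t(sigmaReg)) / 2
  precision <- if (invMode == "pseudoinverse") {
    MASS::ginv(sigmaReg)
  } else {
    if (rcond(sigmaReg) < 1e-12)
      stop(paste("covariance matrix is (near-)singular; supply lambda > 0",
                 "or use invMode = 'pseudoinverse'"), call. = FALSE)
    solve(sigmaReg)
  }
  precision <- (precision + t(precision)) / 2
  new("GaussModel", mu = mu, sigmaReg = sigmaReg, precision = precision,
      lambda = lambda, invMode = invMode,
      theta = chi2Quantile(d, coverage), coverage = coverage,
      d = as.integer(d))
}

#' Squared Mahalanobis distance under a Gaussian description
#'
#' @param model A [GaussModel-class].
#' @param Z matrix of points (rows) or a single vector.
#' @return Numeric vector of squared Mahalanobis distances.
#' @export
gaussScore <- function(model, Z) {
  stopifnot(is(model, "GaussModel"))
  Z <- if (is.null(dim(Z))) matrix(Z, ncol = model@d) else as.matrix(Z)
  if (ncol(Z) != model@d)
    stop("dimension mismatch with the fitted space", call. = FALSE)
  stats::mahalanobis(Z, model@mu, model@precision, inverted = TRUE)
}

#' Accept/reject test points under a Gaussian description
#'
#' @param model A [GaussModel-class].
#' @param Z matrix of points (rows) or a single vector.
#' @return Logical vector, `TRUE` = accepted (Mahalanobis^2 `<= theta`).
#' @examples
#' m <- gaussFit(matrix(rnorm(200), ncol = 2))
#' gaussPredict(m, m@mu)  # TRUE: the mean is always accepted
#' @export
gaussPredict <- function(model, Z) {
  gaussScore(model, Z) <= model@theta
}
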