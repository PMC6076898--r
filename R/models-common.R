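#' Common scoring interface for data description models
#'
#' All three descriptions expose a scalar novelty score (lower = more
#' target-like) and an acceptance threshold, so pipeline code and boundary
#' exports can treat them uniformly: a point is accepted when
#' `ddScore(model, z) <= ddThreshold(model)` (SVDD additionally accepts a
#' thin numerical band around the boundary).
#'
#' @param model A fitted `SVDDModel`, `KNNDDModel` or `GaussModel`.
#' @param Z matrix of points (rows) or a single vector.
#' @return `ddScore`: numeric scores; `ddThreshold`: the scalar acceptance
#'   bound; `ddPredict`: logical accept (`TRUE` = target).
#' @export
setGeneric("ddScore", function(model, Z) standardGeneric("ddScore"))

#' @rdname ddScore
#' @export
setGeneric("ddThreshold", function(model) standardGeneric("ddThreshold"))

#' @rdname ddScore
#' @export
setGeneric("ddPredict", function(model, Z) standardGeneric("ddPredict"))

#' @rdname ddScore
#' @export
setMethod("ddScore", "SVDDModel", function(model, Z) svddDistance2(model, Z))
#' @rdname ddScore
#' @export
setMethod("ddScore", "KNNDDModel", function(model, Z) knnddScore(model, Z))
#' @rdname ddScore
#' @export
setMethod("ddScore", "GaussModel", function(model, Z) gaussScore(model, Z))

#' @rdname ddScore
#' @export
setMethod("ddThreshold", "SVDDModel", function(model) model@radius2)
#' @rdname ddScore
#' @export
setMethod("ddThreshold", "KNNDDModel", function(model) model@threshold)
#' @rdname ddScore
#' @export
setMethod("ddThreshold", "GaussModel", function(model) model@theta)

#' @rdname ddScore
#' @export
setMethod("ddPredict", "SVDDModel", function(model, Z) svddPredict(model, Z))
#' @rdname ddScore
#' @export
setMethod("ddPredict", "KNNDDModel", function(model, Z) knnddPredict(model, Z))
#' @rdname ddScore
#' @export
setMethod("ddPredict", "GaussModel", function(model, Z) gaussPredict(model, Z))

#' Serialize / restore a fitted description model
#'
#' Writes a fitted model to a plain-text YAML key-value file (kernel spec,
#' support vectors and multipliers, mean and covariance, thresholds) so a
#' model fitted once can be reused by the command-line pipeline.
#'
#' @param model A fitted `SVDDModel`, `KNNDDModel` or `GaussModel`.
#' @param path file path.
#' @return `writeModelFile` returns `path` invisibly; `readModelFile`
#'   returns the restored model object.
#' @export
writeModelFile <- function(model, path) {
  lst <- switch(class(model),
    SVDDModel = list(type = "SVDD",
                     kernel = list(kind = model@kernel@kind,
                                   sigma = model@kernel@sigma),
                     supportVectors = apply(model@supportVectors, 1L,
                                            as.numeric, simplify = FALSE),
                     alphas = as.numeric(model@alphas), C = model@C,
                     radius2 = model@radius2, offset = model@offset,
                     info = model@info),
    KNNDDModel = list(type = "KNNDD",
                      training = apply(model@training, 1L, as.numeric,
                                       simplify = FALSE),
                      k = model@k, threshold = model@threshold),
    GaussModel = list(type = "GAUSS", mu = as.numeric(model@mu),
                      sigmaReg = apply(model@sigmaReg, 1L, as.numeric,
                                       simplify = FALSE),
                      lambda = model@lambda, invMode = model@invMode,
                      coverage = model@coverage, theta = model@theta,
                      d = model@d),
    stop("unsupported model class: ", class(model), call. = FALSE))
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname writeModelFile
#' @export
readModelFile <- function(path) {
  lst <- yaml::read_yaml(path)
  rows2mat <- function(x) do.call(rbind, lapply(x, as.numeric))
  switch(lst$type,
    SVDD = new(Class = "SVDDModel", supportVectors = rows2mat(lst$supportVectors),
               alphas = as.numeric(lst$alphas),
               kernel = new("KernelSpec", kind = lst$kernel$kind,
                            sigma = as.numeric(lst$kernel$sigma)),
               C = lst$C, radius2 = lst$radius2, offset = lst$offset,
               info = lst$info),
    KNNDD = new("KNNDDModel", training = rows2mat(lst$training),
                k = as.integer(lst$k), threshold = as.numeric(lst$threshold)),
    GAUSS = {
      sig <- rows2mat(lst$sigmaReg)
      sig <- (sig + t(sig)) / 2
      prec <- if (lst$invMode == "pseudoinverse") MASS::ginv(sig)
              else solve(sig)
      new("GaussModel", mu = as.numeric(lst$mu), sigmaReg = sig,
          precision = (prec + t(prec)) / 2, lambda = lst$lambda,
          invMode = lst$invMode, theta = lst$theta,
          coverage = lst$coverage, d = as.integer(lst$d))
    },
    stop("unknown model type in ", path, call. = FALSE))
}

#' Export a 2-D decision-boundary grid
#'
#' Evaluates a fitted description on a rectangular grid and writes a CSV of
#' `x, y, score, accept` rows for external contour plotting of the decision
#' boundary.
#'
#' @param model a fitted 2-D description model.
#' @param xlim,ylim length-2 bounding-box intervals.
#' @param n grid points per axis (default 60).
#' @param path output CSV path.
#' @return The grid data frame, invisibly (written to `path` if given).
#' @export
exportBoundaryGrid <- function(model, xlim, ylim, n = 60L, path = NULL) {
  gx <- seq(xlim[1], xlim[2], length.out = n)
  gy <- seq(ylim[1], ylim[2], length.out = n)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  df <- data.frame(grid, score = ddScore(model, grid),
                   accept = ddPredict(model, grid))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
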