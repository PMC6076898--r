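#' SpectraSet: a labelled NIR absorbance matrix
#'
#' Container for a set of near-infrared absorbance spectra measured on a
#' common wavenumber grid. Rows of `absorbance` are samples, columns are
#' spectral points; the wavenumber axis is stored high-to-low (as acquired,
#' e.g. 10,000 down to 4,000 cm^-1). Each sample carries a brand label and a
#' unique sample identifier.
#'
#' @slot absorbance numeric matrix, `n_samples x n_points` (absorbance units).
#' @slot wavenumbers numeric vector of length `n_points`, strictly decreasing
#'   (cm^-1).
#' @slot labels character vector of per-sample class/brand labels.
#' @slot sampleIds character vector of unique per-sample identifiers.
#' @slot metadata free-form list (e.g. the axis direction found on disk).
#' @export
setClass("SpectraSet",
  slots = c(absorbance = "matrix", wavenumbers = "numeric",
            labels = "character", sampleIds = "character",
            metadata = "list"))

setValidity("SpectraSet", function(object) {
  msg <- character()
  a <- object@absorbance
  if (!is.numeric(a)) msg <- c(msg, "absorbance must be a numeric matrix")
  else if (!all(is.finite(a))) msg <- c(msg, "absorbance values must all be finite")
  if (length(object@wavenumbers) != ncol(a))
    msg <- c(msg, "length(wavenumbers) must equal ncol(absorbance)")
  if (length(object@wavenumbers) >= 2 && any(diff(object@wavenumbers) >= 0))
    msg <- c(msg, "wavenumbers must be strictly decreasing (stored high-to-low)")
  if (length(object@labels) != nrow(a))
    msg <- c(msg, "length(labels) must equal nrow(absorbance)")
  if (length(object@sampleIds) != nrow(a))
    msg <- c(msg, "length(sampleIds) must equal nrow(absorbance)")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sampleIds must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' Wavenumbers supplied in ascending order are accepted and normalized to the
#' stored descending convention (columns reordered accordingly); the original
#' direction is recorded in `metadata$originalOrder`.
#'
#' @param absorbance numeric matrix (`n_samples x n_points`).
#' @param wavenumbers numeric vector (cm^-1), strictly monotonic.
#' @param labels per-sample labels (recycled if length 1).
#' @param sampleIds optional unique sample identifiers (default `S001`, ...).
#' @param metadata optional list of free-form metadata.
#' @return A [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(matrix(rnorm(12), 3), seq(8000, 5000, length.out = 4), "A")
#' nSamples(s)
#' @export
SpectraSet <- function(absorbance, wavenumbers, labels, sampleIds = NULL,
                       metadata = list()) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) >= 2 && all(diff(wavenumbers) > 0)) {
    ord <- rev(seq_along(wavenumbers))
    wavenumbers <- wavenumbers[ord]
    absorbance <- absorbance[, ord, drop = FALSE]
    metadata$originalOrder <- "ascending"
  } else if (is.null(metadata$originalOrder)) {
    metadata$originalOrder <- "descending"
  }
  n <- nrow(absorbance)
  labels <- as.character(labels)
  if (length(labels) == 1L) labels <- rep(labels, n)
  if (is.null(sampleIds)) sampleIds <- sprintf("S%03d", seq_len(n))
  new("SpectraSet", absorbance = absorbance, wavenumbers = wavenumbers,
      labels = labels, sampleIds = as.character(sampleIds),
      metadata = metadata)
}

#' @describeIn SpectraSet Absorbance matrix (samples x points).
#' @param x,object A `SpectraSet`.
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname SpectraSet
#' @export
setMethod("absorbance", "SpectraSet", function(x) x@absorbance)

#' @describeIn SpectraSet Wavenumber axis (cm^-1, descending).
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectraSet
#' @export
setMethod("wavenumbers", "SpectraSet", function(x) x@wavenumbers)

#' @describeIn SpectraSet Per-sample brand labels.
#' @export
setGeneric("brandLabels", function(x) standardGeneric("brandLabels"))

#' @rdname SpectraSet
#' @export
setMethod("brandLabels", "SpectraSet", function(x) x@labels)

#' @describeIn SpectraSet Per-sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SpectraSet
#' @export
setMethod("sampleIds", "SpectraSet", function(x) x@sampleIds)

#' @describeIn SpectraSet Number of samples.
#' @export
nSamples <- function(x) nrow(x@absorbance)

#' @describeIn SpectraSet Number of spectral points.
#' @export
nPoints <- function(x) ncol(x@absorbance)

#' @describeIn SpectraSet Subset samples by index, id or logical vector.
#' @param i sample index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SpectraSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleIds)
  new("SpectraSet", absorbance = x@absorbance[i, , drop = FALSE],
      wavenumbers = x@wavenumbers, labels = x@labels[i],
      sampleIds = x@sampleIds[i], metadata = x@metadata)
})

setMethod("show", "SpectraSet", function(object) {
  wn <- range(object@wavenumbers)
  cat(sprintf("SpectraSet: %d spectra x %d points (%.1f-%.1f cm^-1)\n",
              nSamples(object), nPoints(object), wn[2], wn[1]))
  tab <- table(object@labels)
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(object)
})

# rbind-combine SpectraSets sharing a wavenumber grid
combineSpectra <- function(sets) {
  stopifnot(length(sets) >= 1L)
  wn <- sets[[1L]]@wavenumbers
  for (s in sets)
    if (!isTRUE(all.equal(s@wavenumbers, wn)))
      stop("all SpectraSets must share the same wavenumber grid", call. = FALSE)
  SpectraSet(do.call(rbind, lapply(sets, absorbance)), wn,
             unlist(lapply(sets, brandLabels), use.names = FALSE),
             unlist(lapply(sets, sampleIds), use.names = FALSE),
             metadata = sets[[1L]]@metadata)
}

# core SNV on a samples-x-points matrix; ids used only for error messages
snvMatrix <- function(m, ids = NULL) {
  m <- as.matrix(m)
  if (ncol(m) < 2L)
    stop("SNV requires at least 2 spectral points per spectrum", call. = FALSE)
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  bad <- which(sdv == 0)
  if (length(bad)) {
    who <- if (is.null(ids)) as.character(bad) else ids[bad]
    stop(sprintf("degenerate spectrum with zero standard deviation: %s",
                 paste(who, collapse = ", ")), call. = FALSE)
  }
  (m - mu) / sdv
}

#' Standard normal variate (SNV) preprocessing
#'
#' Autoscales each spectrum to zero mean and unit standard deviation
#' (sample standard deviation, divisor `n - 1`), removing additive baseline
#' offsets and multiplicative particle-size (scatter) effects. The wavenumber
#' axis and labels are unchanged.
#'
#' @param x A [SpectraSet-class] or a numeric samples-x-points matrix.
#' @return An object of the same kind with each row standardized.
#' @examples
#' snvTransform(matrix(c(1, 2, 3), 1))   # -1 0 1
#' @export
setGeneric("snvTransform", function(x) standardGeneric("snvTransform"))

#' @rdname snvTransform
#' @export
setMethod("snvTransform", "matrix", function(x) snvMatrix(x, rownames(x)))

#' @rdname snvTransform
#' @export
setMethod("snvTransform", "SpectraSet", function(x) {
  out <- x
  out@absorbance <- snvMatrix(x@absorbance, x@sampleIds)
  out
})

#' Read / write spectra as CSV
#'
#' The on-disk format is a plain UTF-8 CSV with header
#' `sample_id,label,<wavenumber_1>,...,<wavenumber_p>` and one sample per
#' row. Wavenumber headers may run in either direction; ascending axes are
#' normalized to the stored descending convention on read.
#'
#' @param path File path.
#' @return `readSpectraCSV` returns a [SpectraSet-class];
#'   `writeSpectraCSV` returns `path` invisibly.
#' @export
readSpectraCSV <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (ncol(df) < 3L || !identical(colnames(df)[1:2], c("sample_id", "label")))
    stop("header must be 'sample_id,label,<wavenumbers...>'", call. = FALSE)
  if (nrow(df) == 0L) stop("no samples", call. = FALSE)
  wn <- suppressWarnings(as.numeric(colnames(df)[-(1:2)]))
  if (anyNA(wn)) stop("non-numeric wavenumber in header", call. = FALSE)
  d <- diff(wn)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("wavenumber header is not strictly monotonic", call. = FALSE)
  raw <- as.matrix(df[, -(1:2), drop = FALSE])
  a <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  if (anyNA(a)) {
    row <- which(apply(a, 1L, anyNA))[1L]
    stop(sprintf("non-numeric absorbance cell in data row %d", row),
         call. = FALSE)
  }
  SpectraSet(a, wn, df$label, df$sample_id)
}

#' @param spectra A [SpectraSet-class] to write.
#' @rdname readSpectraCSV
#' @export
writeSpectraCSV <- function(spectra, path) {
  stopifnot(is(spectra, "SpectraSet"))
  df <- data.frame(sample_id = sampleIds(spectra),
                   label = brandLabels(spectra),
                   absorbance(spectra), check.names = FALSE)
  colnames(df)[-(1:2)] <- format(wavenumbers(spectra), trim = TRUE,
                                 digits = 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
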