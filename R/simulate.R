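#' BrandRecipe: generative model for one brand's NIR spectra
#'
#' A brand is modelled as a fixed sum of Gaussian absorption bands plus
#' per-sample nuisance effects: a multiplicative scatter factor (particle
#' size), an additive baseline (constant offset plus a mild linear tilt
#' across the axis), and white measurement noise. Brands differ in the
#' amplitude ratios of shared bands, emulating different balances of
#' chemical constituents rather than wholly different chemistry.
#'
#' @slot name brand identifier.
#' @slot bandCenters,bandAmplitudes,bandWidths equal-length numeric vectors:
#'   band positions (cm^-1), peak amplitudes (AU, >= 0) and Gaussian sigmas
#'   (cm^-1, > 0).
#' @slot baselineSlopeRange,baselineOffsetRange length-2 intervals for the
#'   per-sample additive baseline (AU).
#' @slot scatterFactorRange length-2 interval in (0, Inf) for the per-sample
#'   multiplicative factor.
#' @slot noiseSd white-noise standard deviation (AU, >= 0).
#' @export
setClass("BrandRecipe",
  slots = c(name = "character", bandCenters = "numeric",
            bandAmplitudes = "numeric", bandWidths = "numeric",
            baselineSlopeRange = "numeric", baselineOffsetRange = "numeric",
            scatterFactorRange = "numeric", noiseSd = "numeric"))

setValidity("BrandRecipe", function(object) {
  msg <- character()
  k <- length(object@bandCenters)
  if (length(object@bandAmplitudes) != k || length(object@bandWidths) != k)
    msg <- c(msg, "band vectors must have equal length")
  if (any(object@bandWidths <= 0)) msg <- c(msg, "bandWidths must be > 0")
  if (any(object@bandAmplitudes < 0)) msg <- c(msg, "bandAmplitudes must be >= 0")
  for (s in c("baselineSlopeRange", "baselineOffsetRange",
              "scatterFactorRange")) {
    r <- slot(object, s)
    if (length(r) != 2L || r[1] > r[2])
      msg <- c(msg, sprintf("%s must be a length-2 interval lo <= hi", s))
  }
  if (object@scatterFactorRange[1] <= 0)
    msg <- c(msg, "scatterFactorRange must lie in (0, Inf)")
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' @param name,bandCenters,bandAmplitudes,bandWidths,baselineSlopeRange,baselineOffsetRange,scatterFactorRange,noiseSd
#'   see slots.
#' @rdname BrandRecipe-class
#' @export
brandRecipe <- function(name, bandCenters, bandAmplitudes, bandWidths,
                        baselineSlopeRange = c(0, 0),
                        baselineOffsetRange = c(0, 0),
                        scatterFactorRange = c(1, 1), noiseSd = 0) {
  new("BrandRecipe", name = name, bandCenters = as.numeric(bandCenters),
      bandAmplitudes = as.numeric(bandAmplitudes),
      bandWidths = as.numeric(bandWidths),
      baselineSlopeRange = as.numeric(baselineSlopeRange),
      baselineOffsetRange = as.numeric(baselineOffsetRange),
      scatterFactorRange = as.numeric(scatterFactorRange),
      noiseSd = as.numeric(noiseSd))
}

setMethod("show", "BrandRecipe", function(object) {
  cat(sprintf("BrandRecipe '%s': %d bands at %s cm^-1, noise sd %.4g AU\n",
              object@name, length(object@bandCenters),
              paste(object@bandCenters, collapse = "/"), object@noiseSd))
  invisible(object)
})

#' Default wavenumber grid
#'
#' 1557 equally spaced points spanning 10,000 down to 4,000 cm^-1 inclusive,
#' matching a typical FT-NIR diffuse-reflectance acquisition.
#' @return Numeric vector of length 1557, descending.
#' @export
defaultGrid <- function() seq(10000, 4000, length.out = 1557)

# shared band structure: C-H combination pair (4266/4335), water combination
# (5175), water / O-H first overtone (6930), C-H second overtone (~8400)
.bandCenters <- c(4266, 4335, 5175, 6930, 8400)
.bandWidths <- c(45, 55, 160, 230, 190)
.bandBaseAmps <- c(0.18, 0.20, 0.60, 0.45, 0.15)

#' Default three-brand recipe library
#'
#' Three brands (`A`, `B`, `C`) sharing the same five absorption bands but
#' differing in amplitude ratios. The single `separation` scale multiplies
#' the brand-specific fractional amplitude offsets: `separation = 0` makes
#' the brands statistically exchangeable, `separation = 1` (default) gives
#' clearly resolvable clusters after SNV + PCA.
#'
#' @param separation non-negative scale for between-brand amplitude
#'   differences.
#' @return Named list of three [BrandRecipe-class] objects.
#' @export
defaultBrandLibrary <- function(separation = 1) {
  assertScalarNumber(separation, "separation", lower = 0)
  deltas <- list(A = c(0, 0, 0, 0, 0),
                 B = c(0.06, -0.05, 0.04, -0.05, 0.08),
                 C = c(-0.05, 0.06, -0.04, 0.05, -0.07))
  lapply(setNames(names(deltas), names(deltas)), function(b)
    brandRecipe(b, .bandCenters,
                .bandBaseAmps * (1 + separation * deltas[[b]]), .bandWidths,
                baselineSlopeRange = c(-0.002, 0.002),
                baselineOffsetRange = c(0, 0.15),
                scatterFactorRange = c(0.7, 1.3), noiseSd = 0.002))
}

# deterministic core; caller controls the RNG state
simulateCore <- function(recipe, n, grid, idPrefix = recipe@name,
                         ampScale = rep(1, n)) {
  p <- length(grid)
  bands <- rep(0, p)
  for (b in seq_along(recipe@bandCenters))
    bands <- bands + recipe@bandAmplitudes[b] *
      exp(-(grid - recipe@bandCenters[b])^2 / (2 * recipe@bandWidths[b]^2))
  u <- (grid - min(grid)) / max(diff(range(grid)), 1)
  scatter <- stats::runif(n, recipe@scatterFactorRange[1],
                          recipe@scatterFactorRange[2])
  offset <- stats::runif(n, recipe@baselineOffsetRange[1],
                         recipe@baselineOffsetRange[2])
  slope <- stats::runif(n, recipe@baselineSlopeRange[1],
                        recipe@baselineSlopeRange[2])
  noise <- matrix(stats::rnorm(n * p, 0, recipe@noiseSd), n, p)
  a <- (ampScale * scatter) %o% bands + offset + slope %o% u + noise
  SpectraSet(a, grid, recipe@name,
             sprintf("%s_%03d", idPrefix, seq_len(n)))
}

#' Simulate NIR spectra from a brand recipe
#'
#' Each spectrum is `scatter * sum_of_Gaussian_bands + baseline + noise`,
#' with the per-sample scatter factor, baseline offset/slope and noise drawn
#' independently. Deterministic for a fixed `seed`.
#'
#' @param recipe A [BrandRecipe-class].
#' @param n Number of spectra (>= 1).
#' @param grid Wavenumber grid (cm^-1), strictly monotonic.
#' @param seed RNG seed.
#' @return A [SpectraSet-class] with `n` rows labelled by the recipe name.
#' @export
simulateSpectra <- function(recipe, n, grid = defaultGrid(), seed = 1) {
  stopifnot(is(recipe, "BrandRecipe"))
  methods::validObject(recipe)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  withSeed(seed, simulateCore(recipe, as.integer(n), as.numeric(grid)))
}

#' Simulate the full three-brand study design
#'
#' Generates the 142-sample design: 48 spectra of brand A, 46 of B and 48 of
#' C on the default 1557-point grid spanning 10,000-4,000 cm^-1. Optionally
#' adds a small per-batch amplitude offset reflecting the batch structure of
#' the sampling campaign (3 batches of A, 2 of B, 3 of C); batch effects are
#' off by default.
#'
#' @param seed RNG seed; all randomness flows from it.
#' @param separation between-brand separation scale
#'   (see [defaultBrandLibrary()]).
#' @param batchEffect standard scale of the per-batch multiplicative
#'   amplitude offset (0 = off, default).
#' @param grid wavenumber grid.
#' @return A [SpectraSet-class] of 142 labelled spectra.
#' @examples
#' s <- simulateStudy(seed = 1)
#' table(brandLabels(s))
#' @export
simulateStudy <- function(seed = 1, separation = 1, batchEffect = 0,
                          grid = defaultGrid()) {
  recipes <- defaultBrandLibrary(separation)
  counts <- c(A = 48L, B = 46L, C = 48L)
  batches <- list(A = rep(1:3, each = 16L), B = rep(1:2, each = 23L),
                  C = rep(1:3, each = 16L))
  withSeed(seed, {
    sets <- lapply(names(counts), function(b) {
      ampScale <- if (batchEffect > 0) {
        off <- stats::rnorm(max(batches[[b]]), 0, batchEffect)
        1 + off[batches[[b]]]
      } else rep(1, counts[[b]])
      simulateCore(recipes[[b]], counts[[b]], as.numeric(grid),
                   ampScale = ampScale)
    })
    combineSpectra(sets)
  })
}
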