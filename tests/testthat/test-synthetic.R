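test_that("brand recipes validate their fields", {
  expect_error(brandRecipe("X", c(5000, 6000), c(1, 1), c(50, -1)),
               "bandWidths")
  expect_error(brandRecipe("X", c(5000, 6000), c(1, -1), c(50, 50)),
               "bandAmplitudes")
  expect_error(brandRecipe("X", 5000, 1, 50, scatterFactorRange = c(-1, 2)),
               "scatterFactorRange")
  expect_error(brandRecipe("X", c(5000, 6000), 1, c(50, 50)),
               "equal length")
})

test_that("default brand library shares bands but differs in amplitude ratios", {
  lib <- defaultBrandLibrary()
  expect_length(lib, 3L)
  expect_identical(names(lib), c("A", "B", "C"))
  centers <- lapply(lib, function(r) r@bandCenters)
  expect_identical(centers$A, centers$B)
  expect_identical(centers$A, centers$C)
  amps <- lapply(lib, function(r) r@bandAmplitudes)
  expect_false(isTRUE(all.equal(amps$A, amps$B)))
  expect_false(isTRUE(all.equal(amps$A, amps$C)))
  expect_false(isTRUE(all.equal(amps$B, amps$C)))

  # degenerate control: zero separation collapses the brands
  lib0 <- defaultBrandLibrary(separation = 0)
  amps0 <- lapply(lib0, function(r) r@bandAmplitudes)
  expect_identical(amps0$A, amps0$B)
  expect_identical(amps0$A, amps0$C)
})

test_that("simulateSpectra is seed-deterministic and exact in the noiseless limit", {
  lib <- defaultBrandLibrary()
  s1 <- simulateSpectra(lib$A, 5, seed = 99)
  s2 <- simulateSpectra(lib$A, 5, seed = 99)
  expect_identical(absorbance(s1), absorbance(s2))
  expect_false(identical(absorbance(s1),
                         absorbance(simulateSpectra(lib$A, 5, seed = 100))))

  # no noise, unit scatter, zero baseline -> the analytic band sum
  r <- brandRecipe("pure", c(5175, 6930), c(0.6, 0.45), c(160, 230))
  grid <- seq(9000, 4500, length.out = 200)
  s <- simulateSpectra(r, 3, grid, seed = 1)
  expected <- 0.6 * exp(-(grid - 5175)^2 / (2 * 160^2)) +
    0.45 * exp(-(grid - 6930)^2 / (2 * 230^2))
  for (i in 1:3)
    expect_equal(unname(absorbance(s)[i, ]), expected, tolerance = 1e-12)

  expect_error(simulateSpectra(lib$A, 0), "positive integer")
})

test_that("the simulated study reproduces the design counts and grid", {
  s <- simulateStudy(seed = 5)
  expect_equal(nSamples(s), 142L)
  expect_equal(nPoints(s), 1557L)
  expect_equal(as.vector(table(brandLabels(s))[c("A", "B", "C")]),
               c(48L, 46L, 48L))
  wn <- wavenumbers(s)
  expect_equal(wn[1], 10000)
  expect_equal(wn[1557], 4000)
  expect_lt(diff(range(diff(wn))), 1e-9)  # uniform spacing
})

test_that("SNV cancels scatter and baseline distortions in the generator", {
  # two draws differing only in scatter/offset (no tilt, no noise) give
  # identical SNV spectra
  r <- brandRecipe("s", c(5175, 6930, 8400), c(0.6, 0.45, 0.15),
                   c(160, 230, 190), baselineOffsetRange = c(0, 0.2),
                   scatterFactorRange = c(0.6, 1.4))
  m <- snvTransform(absorbance(simulateSpectra(r, 6, seed = 2)))
  for (i in 2:6) expect_equal(m[i, ], m[1, ], tolerance = 1e-8)

  # with the default tilt and noise the residual stays at the noise scale
  lib <- defaultBrandLibrary()
  m <- snvTransform(absorbance(simulateSpectra(lib$A, 20, seed = 3)))
  offDiag <- function(x) x[upper.tri(x)]
  expect_gt(min(offDiag(cor(t(m)))), 0.99)
})

test_that("brands separate after SNV at the default separation", {
  s <- simulateStudy(seed = 17)
  m <- snvTransform(absorbance(s))
  lab <- brandLabels(s)
  centroids <- t(sapply(c("A", "B", "C"), function(b)
    colMeans(m[lab == b, , drop = FALSE])))
  between <- min(dist(centroids))
  within95 <- max(sapply(c("A", "B", "C"), function(b) {
    rows <- m[lab == b, , drop = FALSE]
    quantile(as.vector(dist(rows)), 0.95)
  }))
  expect_gt(between, within95)
})
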