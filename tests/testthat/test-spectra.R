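test_that("SpectraSet validates its invariants and normalizes axis direction", {
  s <- toySpectra()
  expect_s4_class(s, "SpectraSet")
  expect_true(all(diff(wavenumbers(s)) < 0))

  # ascending input axis is stored descending, with provenance recorded
  a <- matrix(1:6 + 0.5, 2, 3)
  up <- SpectraSet(a, c(4000, 5000, 6000), c("A", "B"))
  expect_identical(wavenumbers(up), c(6000, 5000, 4000))
  expect_identical(absorbance(up)[, 3], a[, 1])
  expect_identical(up@metadata$originalOrder, "ascending")

  expect_error(SpectraSet(matrix(c(1, Inf, 3, 4), 2), c(9000, 8000),
                          c("A", "B")), "finite")
  expect_error(SpectraSet(matrix(1:4 + 0.1, 2), c(9000, 8000), "A",
                          sampleIds = c("x", "x")), "unique")
  expect_error(SpectraSet(matrix(1:4 + 0.1, 2), c(9000, 8000, 7000),
                          c("A", "B")), "wavenumbers")

  sub <- s[c(1L, 3L)]
  expect_equal(nSamples(sub), 2L)
  expect_identical(sampleIds(sub), sampleIds(s)[c(1, 3)])
})

test_that("SNV centers and scales each spectrum with divisor n-1", {
  expect_equal(drop(snvTransform(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))

  s <- toySpectra(n = 6L, p = 40L)
  out <- snvTransform(s)
  m <- absorbance(out)
  expect_lt(max(abs(rowMeans(m))), 1e-10)
  expect_lt(max(abs(apply(m, 1L, sd) - 1)), 1e-10)
  expect_identical(wavenumbers(out), wavenumbers(s))
  expect_identical(brandLabels(out), brandLabels(s))

  # idempotence
  expect_equal(absorbance(snvTransform(out)), m, tolerance = 1e-12)
})

test_that("SNV rejects degenerate spectra and names the offender", {
  a <- rbind(c(1, 2, 3), c(5, 5, 5))
  s <- SpectraSet(a, c(9000, 8000, 7000), c("A", "A"),
                  sampleIds = c("good", "flat"))
  expect_error(snvTransform(s), "flat")
  expect_error(snvTransform(matrix(5, 1, 3)), "zero standard deviation")
  expect_error(snvTransform(matrix(1, 1, 1)), "at least 2")
})

test_that("SNV removes per-row affine distortion", {
  withSeed(7, {
    for (rep in 1:20) {
      x <- matrix(rnorm(30), 1)
      a <- runif(1, 0.1, 5); b <- rnorm(1, sd = 10)
      expect_equal(snvTransform(a * x + b), snvTransform(x),
                   tolerance = 1e-9)
    }
  })
})

test_that("spectra CSV round-trips and rejects malformed input", {
  s <- toySpectra(n = 3L, p = 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectraCSV(s, path)
  back <- readSpectraCSV(path)
  expect_identical(brandLabels(back), brandLabels(s))
  expect_identical(sampleIds(back), sampleIds(s))
  expect_lt(max(abs(absorbance(back) - absorbance(s))), 1e-9)
  expect_equal(wavenumbers(back), wavenumbers(s), tolerance = 1e-9)

  # shuffled (non-monotonic) wavenumber header
  lines <- readLines(path)
  hdr <- strsplit(lines[1], ",")[[1]]
  lines[1] <- paste(hdr[c(1, 2, 4, 3, 5, 6, 7)], collapse = ",")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, bad)
  expect_error(readSpectraCSV(bad), "monotonic")

  # non-numeric cell carries the row number
  lines <- readLines(path)
  lines[3] <- sub("^([^,]*,[^,]*,)[^,]*", "\\1oops", lines[3])
  writeLines(lines, bad)
  expect_error(readSpectraCSV(bad), "row 2")

  # empty file / header-only file
  writeLines(readLines(path)[1], bad)
  expect_error(readSpectraCSV(bad), "no samples")
})
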