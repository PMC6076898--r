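test_that("the RBF kernel follows the sigma^2 convention", {
  expect_equal(rbfKernel(c(1, 2), c(1, 2), 0.5), 1)
  expect_equal(rbfKernel(c(0, 0), c(1, 0), 1), exp(-1))
  expect_gt(rbfKernel(c(0, 0), c(3, 4), 1e6), 1 - 1e-9)
  expect_error(rbfKernel(c(0, 0), 1, 1), "equal length")
  expect_error(rbfKernel(0, 1, -1), "sigma")
  expect_error(kernelSpec("rbf", -2), "positive")
})

test_that("SVDD handles the single-point and collinear linear-kernel cases", {
  m1 <- svddFit(matrix(c(2, 3), 1), kernelSpec("linear"), f = 0.5)
  expect_equal(m1@alphas, 1)
  expect_equal(m1@radius2, 0)
  expect_true(svddPredict(m1, c(2, 3)))
  expect_equal(svddDistance2(m1, c(2, 3)), 0, tolerance = 1e-12)

  # 1-D {0, 1, 2}: center 1, R = 1, SVs = endpoints
  m <- svddFit(matrix(c(0, 1, 2), 3), kernelSpec("linear"), f = 0.1)
  expect_equal(m@radius2, 1, tolerance = 1e-6)
  expect_equal(sort(drop(m@supportVectors)), c(0, 2), tolerance = 1e-9)
  expect_equal(svddDistance2(m, 5), 16, tolerance = 1e-6)
  expect_equal(svddDistance2(m, 1), 0, tolerance = 1e-6)
  expect_true(all(svddPredict(m, matrix(c(0, 1, 2), 3))))
  expect_false(svddPredict(m, 5))
})

test_that("linear-kernel SVDD equals the brute-force minimum enclosing ball", {
  withSeed(21, {
    for (rep in 1:5) {
      X <- matrix(rnorm(16), 8, 2)
      m <- svddFit(X, kernelSpec("linear"), f = 0.05)  # C > 1: hard margin
      ball <- mebOracle(X)
      expect_equal(m@radius2, ball$radius2, tolerance = 1e-6)
      center <- drop(t(m@alphas) %*% m@supportVectors)
      expect_equal(center, ball$center, tolerance = 1e-4,
                   ignore_attr = TRUE)
    }
  })
})

test_that("the SMO dual optimum matches a generic QP solver on small instances", {
  withSeed(33, {
    for (rep in 1:5) {
      n <- sample(5:12, 1)
      X <- matrix(rnorm(2 * n), n, 2)
      f <- runif(1, 0.15, 0.6)
      for (kern in list(kernelSpec("rbf", 1.5), kernelSpec("linear"))) {
        K <- nirdd:::kernelMatrix(X, X, kern)
        aSMO <- nirdd:::svddSolveDual(K, 1 / (n * f))
        aQP <- qpDualOracle(K, 1 / (n * f))
        expect_equal(svddDualObjective(K, aSMO), svddDualObjective(K, aQP),
                     tolerance = 1e-6)
        # KKT residual at convergence
        g <- diag(K) - 2 * drop(K %*% aSMO)
        C <- 1 / (n * f)
        up <- aSMO < C - 1e-10; dn <- aSMO > 1e-10
        expect_lt(max(g[up]) - min(g[dn]), 1e-7)
      }
    }
  })
})

test_that("RBF SVDD decisions match a nu-one-class-SVM oracle", {
  withSeed(44, {
    for (rep in 1:10) {
      X <- matrix(rnorm(60), 30, 2)
      Z <- matrix(rnorm(40, sd = 1.5), 20, 2)
      m <- svddFit(X, kernelSpec("rbf", 2), f = 0.1)
      oc <- e1071::svm(X, type = "one-classification", kernel = "radial",
                       gamma = 1 / 4, nu = 0.1, scale = FALSE,
                       tolerance = 1e-7)
      P <- rbind(X, Z)
      dec <- c(attr(predict(oc, P, decision.values = TRUE),
                    "decision.values"))
      # exclude the thin numerical tie band around each solver's boundary
      off <- abs(svddDistance2(m, P) - m@radius2) > 1e-6 & abs(dec) > 1e-6
      expect_gt(mean(off), 0.75)
      expect_identical(svddPredict(m, P)[off], unname(dec[off] > 0))
    }
  })
})

test_that("SVDD respects the rejection-fraction contract and boundary geometry", {
  withSeed(55, {
    for (f in c(0.05, 0.1, 0.3)) {
      X <- matrix(rnorm(50), 25, 2)
      m <- svddFit(X, kernelSpec("rbf", 1.5), f = f)
      n <- m@info$n
      expect_lte(m@info$nTrainRejected / n, f + 1 / n)
      expect_lte(m@info$nBounded, ceiling(f * n))
      # unbounded SVs sit exactly on the sphere
      unb <- m@alphas < m@C * (1 - 1e-8)
      d2 <- svddDistance2(m, m@supportVectors[unb, , drop = FALSE])
      expect_lt(max(abs(d2 - m@radius2)), 1e-6)
      # only bounded SVs may fall outside the sphere (KKT: interior and
      # boundary points all satisfy distance^2 <= R^2)
      expect_lte(m@info$nTrainRejected, m@info$nBounded)
      expect_false(svddPredict(m, c(50, 50)))
    }
  })
})

test_that("large-width RBF SVDD collapses to the rigid hypersphere", {
  withSeed(66, {
    X <- matrix(rnorm(40), 20, 2)
    Z <- matrix(rnorm(60, sd = 2), 30, 2)
    diam <- sqrt(max(nirdd:::sqDistMatrix(X, X)))
    big <- svddFit(X, kernelSpec("rbf", 100 * diam), f = 0.05)
    lin <- svddFit(X, kernelSpec("linear"), f = 0.05)
    # support vectors lie exactly on the enclosing ball, where the
    # O((d/sigma)^4) kernel-expansion residue can flip the sign; compare
    # every point outside that tie band (relative: the large-width model's
    # feature-space distances all carry the 2/sigma^2 shrinkage)
    P <- rbind(X, Z)
    off <- abs(svddDistance2(lin, P) - lin@radius2) > 1e-3 * lin@radius2 &
           abs(svddDistance2(big, P) - big@radius2) > 1e-3 * big@radius2
    expect_gt(mean(off), 0.8)
    expect_identical(svddPredict(big, P)[off], svddPredict(lin, P)[off])
  })
})

test_that("an all-bounded solution falls back to the max SV distance with a warning", {
  X <- matrix(c(0, 0.01, 10, 10.01), 4)
  expect_warning(m <- svddFit(X, kernelSpec("linear"), f = 0.5),
                 "no unbounded support vector")
  expect_gte(m@radius2, 0)
})

test_that("KNNDD scores the hand-worked distance ratios", {
  m <- knnddFit(rbind(c(0, 0), c(1, 0)), k = 1)
  expect_equal(knnddScore(m, c(0.4, 0)), 0.4)
  expect_true(knnddPredict(m, c(0.4, 0)))
  expect_equal(knnddScore(m, c(3, 0)), 2)
  expect_false(knnddPredict(m, c(3, 0)))
  # duplicating a training point is always accepted
  expect_equal(knnddScore(m, c(1, 0)), 0)
  expect_true(knnddPredict(m, c(1, 0)))

  # zero denominator: duplicated training pair
  dup <- knnddFit(rbind(c(0, 0), c(0, 0)), k = 1)
  expect_identical(knnddScore(dup, c(0.5, 0)), Inf)
  expect_false(knnddPredict(dup, c(0.5, 0)))
  expect_equal(knnddScore(dup, c(0, 0)), 0)
  expect_true(knnddPredict(dup, c(0, 0)))

  expect_error(knnddFit(matrix(rnorm(6), 3), k = 3), "k must satisfy")

  withSeed(5, {
    Xtr <- matrix(rnorm(30), 15, 2)
    # k = 1 with threshold 1 accepts every training duplicate; scores are
    # zero up to floating cancellation in the cross-distance expansion
    m1 <- knnddFit(Xtr, k = 1)
    expect_lt(max(knnddScore(m1, Xtr)), 1e-3)
    expect_true(all(knnddPredict(m1, Xtr)))
    # larger k: scores stay finite and non-negative, decisions deterministic
    m2 <- knnddFit(Xtr, k = 2)
    sc <- knnddScore(m2, Xtr)
    expect_true(all(is.finite(sc) & sc >= 0))
    expect_identical(knnddPredict(m2, Xtr), knnddPredict(m2, Xtr))
  })
})

test_that("chi-square thresholds match numerical CDF inversion", {
  expect_equal(chi2Quantile(2, 0.95), 5.9915, tolerance = 1e-4)
  expect_equal(chi2Quantile(1, 0.95), 3.8415, tolerance = 1e-4)
  for (d in c(1, 2, 5)) for (p in c(0.5, 0.9, 0.99))
    expect_equal(chi2Quantile(d, p), chi2QuantileOracle(d, p),
                 tolerance = 1e-6)
  expect_lt(chi2Quantile(2, 1e-8), 1e-6)   # coverage -> 0+ limit
  expect_error(chi2Quantile(2, 1.2), "coverage")
  expect_error(chi2Quantile(0, 0.95), "d")
})

test_that("the Gaussian description accepts its mean and attains coverage", {
  withSeed(77, {
    X <- matrix(rnorm(8000), ncol = 2)
    m <- gaussFit(X, coverage = 0.95)
    expect_true(gaussPredict(m, m@mu))
    expect_equal(gaussScore(m, m@mu), 0, tolerance = 1e-10)
    expect_equal(mean(gaussPredict(m, X)), 0.95, tolerance = 0.02)
    # deterministic scoring
    expect_identical(gaussScore(m, X[1:50, ]), gaussScore(m, X[1:50, ]))
  })
})

test_that("rank-deficient covariance errors in regularized mode, scores in pseudoinverse mode", {
  x <- seq(-1, 1, length.out = 10)
  X <- cbind(x, 2 * x)  # exactly 1-D in 2-D space
  expect_error(gaussFit(X, lambda = 0), "singular")
  m <- gaussFit(X, lambda = 0, invMode = "pseudoinverse")
  expect_true(all(is.finite(gaussScore(m, X))))
  expect_true(gaussPredict(m, c(0, 0)))
})

test_that("fitted models survive a YAML round trip", {
  withSeed(88, {
    X <- matrix(rnorm(30), 15, 2)
    Z <- matrix(rnorm(20, sd = 1.5), 10, 2)
    models <- list(svddFit(X, kernelSpec("rbf", 1.5), f = 0.2),
                   knnddFit(X, k = 1), gaussFit(X))
    for (m in models) {
      path <- withr::local_tempfile(fileext = ".yml")
      writeModelFile(m, path)
      back <- readModelFile(path)
      expect_equal(ddScore(back, Z), ddScore(m, Z), tolerance = 1e-9)
      expect_identical(ddPredict(back, Z), ddPredict(m, Z))
      expect_equal(ddThreshold(back), ddThreshold(m), tolerance = 1e-12)
    }
  })
})
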