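test_that("correlation distance has the expected anchors", {
  set.seed(1)
  X <- matrix(rnorm(40), 4, 10)
  D <- correlationDistance(rbind(X, -X[1, , drop = FALSE]))
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_equal(unname(D[1, 5]), 2)               # row vs its negation
  expect_error(correlationDistance(rbind(X, 0)), "constant row")
})

test_that("rescaled template rows are clustered perfectly at distance 0", {
  set.seed(2)
  t1 <- rnorm(12); t2 <- rnorm(12)
  X <- rbind(2 * t1, 0.5 * t1, 7 * t1, 3 * t2, 0.1 * t2, t2)
  km <- kmeansCorrelation(X, 2, nInit = 20, seed = 3)
  expect_equal(adjustedRandIndex(km$labels, c(1, 1, 1, 2, 2, 2)), 1)
  expect_lt(km$totalDistance, 1e-10)
  expect_error(kmeansCorrelation(X, 7, seed = 1), "exceeds")
})

test_that("K-means with restarts attains the exhaustive-search optimum", {
  set.seed(4)
  for (rep in 1:8) {
    X <- matrix(rnorm(40), 8, 5)
    km <- kmeansCorrelation(X, 2, nInit = 100, seed = rep)
    oracle <- bruteForce2Means(X)
    expect_equal(km$totalDistance, oracle$obj, tolerance = 1e-8)
    expect_equal(adjustedRandIndex(km$labels, oracle$labels), 1)
  }
})

test_that("the Lloyd objective is non-increasing within every restart", {
  set.seed(5)
  for (rep in 1:10) {
    X <- matrix(rnorm(30 * 8), 30, 8)
    km <- kmeansCorrelation(X, 3, nInit = 5, seed = rep)
    expect_true(all(diff(km$trace) <= 1e-8))
  }
})

test_that("ARI matches oracles and is invariant to label renaming", {
  skip_if_not_installed("mclust")
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjustedRandIndex(a, b), mclust::adjustedRandIndex(a, b))
  expect_equal(adjustedRandIndex(a, b), pairCountARI(a, b))
  expect_equal(adjustedRandIndex(a, a), 1)
  expect_equal(adjustedRandIndex(a, 3 - a), adjustedRandIndex(a, a))
  expect_error(adjustedRandIndex(a, b[-1]), "length")
  set.seed(6)
  for (i in 1:20) {
    x <- sample(3, 25, replace = TRUE)
    y <- sample(4, 25, replace = TRUE)
    expect_equal(adjustedRandIndex(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
})

test_that("ARI of independent random labelings is centered on zero", {
  set.seed(7)
  vals <- replicate(1000, adjustedRandIndex(sample(2, 40, replace = TRUE),
                                            sample(2, 40, replace = TRUE)))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("SigClust rejects separated clusters and respects invariances", {
  set.seed(8)
  X2 <- rbind(matrix(rnorm(40 * 15), 40), matrix(rnorm(40 * 15, 10), 40))
  sc <- sigClust(X2, nSim = 200, seed = 1)
  expect_equal(sigClustP(sc), 1 / 201)          # minimum attainable
  # cluster index is invariant to duplicating the data
  X <- matrix(rnorm(25 * 6), 25, 6)
  ci1 <- normsub:::.clusterIndex(X, 20)
  ci2 <- normsub:::.clusterIndex(rbind(X, X), 20)
  expect_equal(ci1, ci2, tolerance = 1e-8)
  expect_error(sigClust(matrix(1, 20, 5)), "constant")
  expect_warning(sigClust(matrix(rnorm(200), 20), nSim = 50), "unstable")
})

test_that("ensemble voting finds the planted number of subtypes", {
  set.seed(9)
  tpl <- matrix(rnorm(3 * 12), 3)
  X3 <- tpl[rep(1:3, each = 25), ] + matrix(rnorm(75 * 12, 0, 0.4), 75)
  r3 <- selectKEnsemble(X3, kRange = 2:6, nInit = 20, seed = 4)
  expect_equal(kSelected(r3), 3L)
  expect_equal(unname(ensembleVotes(r3)["3"]), max(ensembleVotes(r3)))
  # two opposite-pattern subtypes from the generator
  co <- generateCohort(cohortConfig(nSites = 2, nHCPerSite = 5,
                                    nPatPerSite = 50, nRegions = 30,
                                    seed = 12))
  pt <- participants(co)
  truth <- groundTruth(co)
  pat <- pt$group != "HC"
  # deviations proxy: residual z-scores against the HC-free generative mean
  Zlike <- scale(gmvMatrix(co)[pat, ])
  r2 <- selectKEnsemble(Zlike, kRange = 2:5, nInit = 30, seed = 5)
  expect_equal(kSelected(r2), 2L)
  expect_gte(adjustedRandIndex(subtypeLabels(r2),
                               pt$subtype_truth[pat]), 0.9)
  expect_equal(sum(ensembleVotes(r2)), length(r2@indexBest))
})

test_that("stability validation behaves at its anchors", {
  set.seed(10)
  co <- generateCohort(cohortConfig(nSites = 3, nHCPerSite = 5,
                                    nPatPerSite = 30, nRegions = 24,
                                    seed = 14))
  pt <- participants(co)
  pat <- pt$group != "HC"
  Z <- scale(gmvMatrix(co)[pat, ])
  ref <- kmeansCorrelation(Z, 2, nInit = 30, seed = 6)$labels
  # same data, same seed: self-comparison is exact
  again <- kmeansCorrelation(Z, 2, nInit = 30, seed = 6)$labels
  expect_equal(adjustedRandIndex(ref, again), 1)
  st <- stabilityValidation(Z, ref, mode = "subsample", frac = 0.9,
                            reps = 20, nInit = 10, seed = 7)
  expect_gte(st$meanARI, 0.95)
  expect_true(all(st$ari >= -1 & st$ari <= 1))
  lo <- stabilityValidation(Z, ref, mode = "loso", sites = pt$site[pat],
                            nInit = 10, seed = 8)
  expect_length(lo$ari, 3)
  expect_gte(min(lo$ari), 0.9)
  # a site holding only one subtype still yields a defined ARI
  sites2 <- pt$site[pat]
  truth <- pt$subtype_truth[pat]
  sites2[truth == "subtype1" & sites2 == "site01"] <- "site02"
  lo2 <- stabilityValidation(Z, ref, mode = "loso", sites = sites2,
                             nInit = 10, seed = 9)
  expect_true(all(is.finite(lo2$ari)))
  expect_error(stabilityValidation(Z, ref, mode = "loso"), "site labels")
})

test_that("label alignment solves the confusion-matrix assignment", {
  a <- c(2, 2, 2, 1, 1, 3, 3)
  ref <- c(1, 1, 1, 3, 3, 2, 2)
  expect_equal(alignClusterLabels(a, ref), ref)
  set.seed(11)
  for (i in 1:10) {
    lab <- sample(4, 30, replace = TRUE)
    perm <- sample(4)
    expect_equal(alignClusterLabels(perm[lab], lab), lab)
  }
})
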