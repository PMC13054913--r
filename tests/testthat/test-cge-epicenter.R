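test_that("CGE construction clips negatives and keeps identity at 1", {
  base <- rnorm(20)
  expr <- rbind(a = base, b = base, c = -base, d = rnorm(20))
  W <- buildCGE(expr)
  expect_equal(W["a", "b"], 1, tolerance = 1e-12)
  expect_equal(W["a", "c"], 0)                 # anticorrelated -> clipped
  expect_true(all(W >= 0) && all(diag(W) == 0))
  expect_equal(W, t(W))
  expect_error(buildCGE(rbind(a = rep(1, 20), b = base)), "constant")
  expect_error(buildCGE(matrix(rnorm(4), 2, 2)), "3 genes")
})

test_that("neighbor deviation matches the hand-computed formula", {
  W <- matrix(0, 3, 3, dimnames = list(paste0("R", 1:3), paste0("R", 1:3)))
  W["R1", "R2"] <- W["R2", "R1"] <- 0.5
  W["R1", "R3"] <- W["R3", "R1"] <- 0.2
  nd <- neighborDeviation(W, c(1, 2, -1))
  expect_equal(unname(nd$dTilde["R1"]), (0.5 * 2 + 0.2 * (-1)) / 2)
  expect_equal(unname(nd$dTilde["R2"]), 0.5 * 1 / 1)
  expect_equal(unname(nd$dTilde["R3"]), 0.2 * 1 / 1)
  expect_equal(unname(nd$neighborCount), c(2, 1, 1))
  # binary weights + constant map: averaging identity
  Wb <- matrix(1, 4, 4); diag(Wb) <- 0
  ndb <- neighborDeviation(Wb, rep(3.3, 4))
  expect_equal(unname(ndb$dTilde), rep(3.3, 4))
  # isolated region is undefined
  Wi <- Wb; Wi[4, ] <- 0; Wi[, 4] <- 0
  ndi <- neighborDeviation(Wi, rnorm(4))
  expect_true(is.na(ndi$dTilde[4]))
  expect_length(ndi$undefinedRegions, 1)
  expect_error(neighborDeviation(Wb, rnorm(3)), "mismatch")
})

test_that("neighbor deviation is linear in the abnormality map", {
  set.seed(1)
  expr <- matrix(rnorm(30 * 50), 30, 50)
  W <- buildCGE(expr)
  d1 <- rnorm(30); d2 <- rnorm(30)
  ndSum <- neighborDeviation(W, 2 * d1 - 3 * d2)$dTilde
  ndLin <- 2 * neighborDeviation(W, d1)$dTilde -
    3 * neighborDeviation(W, d2)$dTilde
  expect_equal(ndSum, ndLin, tolerance = 1e-10)
})

test_that("Steiger Z is zero for equal correlations and detects planted gaps", {
  st <- steigerZ(0.5, 0.5, 0.3, 0.2, 0.2, 0.3, 100)
  expect_equal(st$z, 0)
  expect_equal(st$p, 1)
  expect_error(steigerZ(0.5, 0.5, 0.3, 0.2, 0.2, 0.3, 5), "too small")
  # strong diffusion coupling vs none: Z favors the diffused map
  set.seed(2)
  co <- generateCohort(cohortConfig(seed = 18))
  as <- generateMolecularAssets(groundTruth(co), nGenes = 150,
                                nCommunities = 6, seed = 3)
  W <- buildCGE(as$expression)
  comm <- as$truth$communityAssignment
  epis <- names(comm)[comm == 1][1:3]
  dSub <- injectEpicenterPattern(W, epis, -1, beta = 0.6, nSteps = 4) +
    rnorm(nrow(W), 0, 0.01)
  dAll <- rnorm(nrow(W))
  cc <- couplingAndCompare(dSub, dAll, W)
  expect_gt(cc$rSubtype, cc$rAll)
  expect_gt(cc$steigerZ, 2)
})

test_that("epicenter ranking handles the degenerate and equivariant cases", {
  set.seed(3)
  # constant map on a binary-weight graph: every rank ties at (n+1)/2,
  # nothing significant (with graded weights dTilde varies with the mean
  # positive weight even for constant d)
  Wb <- (matrix(runif(24 * 24), 24) > 0.5) * 1
  Wb <- Wb * t(Wb); diag(Wb) <- 0
  rownames(Wb) <- colnames(Wb) <- sprintf("R%03d", 1:24)
  et0 <- suppressWarnings(epicenterTest(Wb, rep(1, 24), nPerm = 200,
                                        seed = 4))
  expr <- matrix(rnorm(24 * 60), 24, 60)
  rownames(expr) <- sprintf("R%03d", 1:24)
  W <- buildCGE(expr)
  tab0 <- epicenterTable(et0)
  expect_true(all(tab0$meanRank == (nrow(tab0) + 1) / 2))
  expect_false(any(tab0$isEpicenter))
  # permuting regions of W and d together permutes the result identically
  d <- rnorm(24)
  perm <- sample(24)
  et1 <- suppressWarnings(epicenterTest(W, d, nPerm = 300, seed = 5))
  et2 <- suppressWarnings(epicenterTest(W[perm, perm], d[perm],
                                        nPerm = 300, seed = 5))
  t1 <- epicenterTable(et1); t2 <- epicenterTable(et2)
  m1 <- setNames(t1$meanRank, t1$region)
  m2 <- setNames(t2$meanRank, t2$region)
  expect_equal(m1[names(m2)], m2)
  expect_warning(epicenterTest(W, d, nPerm = 500, seed = 1), "resolution")
})

test_that("planted epicenters are recovered from diffusion maps", {
  co <- generateCohort(cohortConfig(seed = 31))
  as <- generateMolecularAssets(groundTruth(co), nGenes = 200,
                                nCommunities = 10, seed = 8)
  W <- buildCGE(as$expression)
  comm <- as$truth$communityAssignment
  set.seed(13)
  epis <- sample(names(comm)[comm == 3], 3)
  d <- injectEpicenterPattern(W, epis, amplitude = -1, beta = 0.6,
                              nSteps = 4)
  d <- d + rnorm(length(d), 0, 0.02 * sd(d))
  et <- epicenterTest(W, d, direction = "ascending", nPerm = 1000,
                      seed = 9)
  tab <- epicenterTable(et)
  topDecile <- tab$region[rank(tab$meanRank) <= ceiling(nrow(tab) / 10)]
  expect_true(all(epis %in% topDecile))
  expect_gte(sum(tab$p[tab$region %in% epis] < 0.01), 2)
  # positive-amplitude epicenters need the descending direction
  dPos <- injectEpicenterPattern(W, epis, amplitude = 1, beta = 0.6,
                                 nSteps = 4)
  etP <- epicenterTest(W, dPos, direction = "descending", nPerm = 1000,
                       seed = 10)
  tabP <- epicenterTable(etP)
  expect_true(all(epis %in%
                    tabP$region[rank(tabP$meanRank) <=
                                  ceiling(nrow(tabP) / 10)]))
})

test_that("coupling strengthens with the diffusion weight", {
  co <- generateCohort(cohortConfig(seed = 31))
  as <- generateMolecularAssets(groundTruth(co), nGenes = 200,
                                nCommunities = 6, seed = 8)
  W <- buildCGE(as$expression)
  set.seed(14)
  meanR <- sapply(c(0, 0.3, 0.6), function(b) {
    mean(sapply(1:8, function(s) {
      d <- injectEpicenterPattern(W, sample(nrow(W), 3), -1, b, 4)
      nd <- neighborDeviation(W, d)$dTilde
      cor(d, nd, use = "complete.obs")
    }))
  })
  expect_true(all(diff(meanR) > 0))
})

test_that("CGE round-trips through its TSV dialect", {
  set.seed(15)
  expr <- matrix(rnorm(10 * 30), 10, 30)
  rownames(expr) <- sprintf("R%03d", 1:10)
  W <- buildCGE(expr)
  tmp <- tempfile(fileext = ".tsv")
  writeCGE(W, tmp)
  expect_equal(readCGE(tmp), W, tolerance = 1e-12)
})
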