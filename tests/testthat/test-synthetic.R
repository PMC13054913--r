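test_that("cohort generation is deterministic and validates its config", {
  cfg <- cohortConfig(nSites = 2, nHCPerSite = 10, nPatPerSite = 10,
                      nRegions = 12, seed = 99)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(gmvMatrix(a), gmvMatrix(b))
  expect_identical(participants(a), participants(b))
  expect_error(cohortConfig(nSites = 0), "nSites")
  expect_error(cohortConfig(patternFraction = 0.7), "patternFraction")
  expect_error(cohortConfig(nRegions = 100, patternFraction = 0.005),
               "patternFraction")
})

test_that("null subtype effect leaves patients at the HC mean", {
  co <- generateCohort(cohortConfig(nSites = 2, nHCPerSite = 100,
                                    nPatPerSite = 100, nRegions = 10,
                                    subtypeEffect = 0, siteShiftSd = 0,
                                    siteScaleRange = c(1, 1), seed = 4))
  pt <- participants(co)
  m <- gmvMatrix(co)
  diff <- colMeans(m[pt$group != "HC", ]) - colMeans(m[pt$group == "HC", ])
  # Monte-Carlo error of a mean difference at n = 200/200, sd 0.5
  expect_lt(max(abs(diff)), 4 * 0.5 * sqrt(1 / 200 + 1 / 200))
})

test_that("disabling site effects equalizes per-region site means", {
  co <- generateCohort(cohortConfig(nSites = 3, nHCPerSite = 150,
                                    nPatPerSite = 1, nRegions = 8,
                                    betaAge = 0, betaSex = 0,
                                    siteShiftSd = 0,
                                    siteScaleRange = c(1, 1), seed = 5))
  pt <- participants(co)
  m <- gmvMatrix(co)
  spread <- apply(m, 2, function(y) diff(range(tapply(y, pt$site, mean))))
  expect_lt(max(spread), 5 * 0.5 / sqrt(150))
})

test_that("planted subtypes separate strongly on pattern regions", {
  co <- generateCohort(cohortConfig(seed = 1))  # 4 sites, 50+50, effect 1.5
  pt <- participants(co)
  truth <- groundTruth(co)
  m <- gmvMatrix(co)
  score <- m[, names(truth$pattern1)] %*% truth$pattern1
  t1 <- t.test(score[pt$subtype_truth == "subtype1"],
               score[pt$subtype_truth == "subtype2"])
  expect_gt(abs(t1$statistic), 5)
})

test_that("generated age effects are recovered by regression", {
  # unit site scaling: the OLS standard errors used for the band assume
  # homoskedastic residuals
  co <- generateCohort(cohortConfig(nSites = 2, nHCPerSite = 150,
                                    nPatPerSite = 1, nRegions = 10,
                                    siteScaleRange = c(1, 1), seed = 6))
  pt <- participants(co)
  hc <- pt$group == "HC"
  m <- gmvMatrix(co)[hc, ]
  truth <- groundTruth(co)
  for (g in seq_len(ncol(m))) {
    fit <- summary(lm(m[, g] ~ pt$age[hc] + pt$sex[hc] +
                        factor(pt$site[hc])))
    est <- fit$coefficients["pt$age[hc]", ]
    # 3.5 SE keeps the family miss rate over 10 regions near the
    # per-region rate of a 3 SE band
    expect_lt(abs(est["Estimate"] - truth$betaAge[g]),
              3.5 * est["Std. Error"])
  }
})

test_that("noiseless single-receptor map reproduces the pattern", {
  co <- generateCohort(cohortConfig(nSites = 2, nHCPerSite = 10,
                                    nPatPerSite = 10, nRegions = 20,
                                    seed = 3))
  as <- generateMolecularAssets(groundTruth(co), nGenes = 20,
                                nReceptors = 1, mapNoiseSd = 0,
                                nuisanceSd = 0, patternLoadings = 1,
                                patternSupport = "full", seed = 2)
  p1 <- as.numeric(groundTruth(co)$pattern1)
  z <- (p1 - mean(p1)) / sd(p1)
  expect_equal(unname(receptorDensities(as$atlas)[, 1]), z,
               tolerance = 1e-12)
})

test_that("expression communities produce a modular CGE", {
  co <- generateCohort(cohortConfig(nSites = 2, nHCPerSite = 10,
                                    nPatPerSite = 10, nRegions = 30,
                                    seed = 7))
  # zero gene-level noise: CGE exactly block-constant
  as0 <- generateMolecularAssets(groundTruth(co), nGenes = 50,
                                 withinGeneNoiseSd = 0, seed = 7)
  W0 <- buildCGE(as0$expression)
  comm <- as0$truth$communityAssignment
  within <- W0[comm == 1, comm == 1]
  expect_true(all(abs(within[upper.tri(within)] - 1) < 1e-12))
  between <- W0[comm == 1, comm == 2]
  expect_lt(diff(range(between)), 1e-12)
  # noisy case: within-community weights dominate between
  as1 <- generateMolecularAssets(groundTruth(co), nGenes = 200, seed = 7)
  W1 <- buildCGE(as1$expression)
  comm1 <- as1$truth$communityAssignment
  same <- outer(comm1, comm1, "==")
  diag(same) <- NA
  expect_gt(mean(W1[same & !is.na(same)]),
            mean(W1[!same & !is.na(same)]))
})

test_that("epicenter diffusion obeys its boundary cases", {
  W <- matrix(0.5, 6, 6); diag(W) <- 0
  rownames(W) <- colnames(W) <- paste0("R", 1:6)
  d0 <- injectEpicenterPattern(W, "R2", amplitude = 1, beta = 0,
                               nSteps = 25)
  expect_equal(unname(d0), c(0, 1, 0, 0, 0, 0))
  dz <- injectEpicenterPattern(W, "R2", amplitude = 1, beta = 0.7,
                               nSteps = 0)
  expect_equal(unname(dz), c(0, 1, 0, 0, 0, 0))
  # complete equal-weight graph: long diffusion converges to the uniform
  # mean of the initial mass (1/n per region)
  dinf <- injectEpicenterPattern(W, "R2", amplitude = 1, beta = 0.5,
                                 nSteps = 400)
  expect_equal(unname(dinf), rep(1 / 6, 6), tolerance = 1e-6)
  # isolated region keeps its value, with a warning
  W2 <- W; W2[6, ] <- 0; W2[, 6] <- 0
  expect_warning(
    d6 <- injectEpicenterPattern(W2, "R6", amplitude = -2, beta = 0.5,
                                 nSteps = 10),
    "propagate unchanged")
  expect_equal(unname(d6[6]), -2)
  expect_error(injectEpicenterPattern(W, character(0), 1, 0.5, 5),
               "nonempty")
  expect_error(injectEpicenterPattern(W, "R1", 1, beta = 1, 5), "beta")
})
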