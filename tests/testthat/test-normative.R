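test_that("constant targets give a constant predictive mean", {
  n <- 30
  covs <- data.frame(age = runif(n, 20, 60), sex = rep(c(0, 1), n / 2))
  m <- cbind(A = rep(5, n), B = rnorm(n, 2))
  mod <- fitNormative(m, covs, nRestarts = 1, seed = 2)
  Z <- deviationZScores(mod, m, covs)
  expect_equal(unname(Z[, "A"]), rep(0, n))   # equals its own prediction
})

test_that("a linear age trend is learned (SMSE < 1 on held-out controls)", {
  set.seed(10)
  n <- 120
  covs <- data.frame(age = runif(n, 18, 65),
                     sex = rbinom(n, 1, 0.5))
  y <- cbind(R1 = 0.05 * covs$age + rnorm(n, 0, 0.5),
             R2 = -0.04 * covs$age + 0.3 * covs$sex + rnorm(n, 0, 0.5))
  tr <- 1:80; te <- 81:120
  mod <- fitNormative(y[tr, ], covs[tr, ], nRestarts = 2, seed = 5)
  Dcross <- normsub:::.predGrid(mod, covs[te, ])
  for (g in 1:2) {
    pr <- normsub:::.gpPredictRegion(mod@models[[g]], Dcross, length(te))
    smse <- sum((y[te, g] - pr$mean)^2) /
      sum((y[te, g] - mean(y[te, g]))^2)
    expect_lt(smse, 1)
  }
})

test_that("refitting with the same seed reproduces hyperparameters", {
  co <- smallCohort()
  m1 <- fitNormative(co, nRestarts = 2, seed = 9)
  m2 <- fitNormative(co, nRestarts = 2, seed = 9)
  expect_identical(normativeHyperparameters(m1),
                   normativeHyperparameters(m2))
})

test_that("held-out controls have calibrated deviations", {
  co <- generateCohort(cohortConfig(nSites = 2, nHCPerSite = 120,
                                    nPatPerSite = 1, nRegions = 8,
                                    siteShiftSd = 0,
                                    siteScaleRange = c(1, 1), seed = 13))
  pt <- participants(co)
  hc <- which(pt$group == "HC")
  set.seed(1)
  te <- sample(hc, 60); tr <- setdiff(hc, te)
  m <- gmvMatrix(co)
  mod <- fitNormative(m[tr, ], pt[tr, c("age", "sex")], nRestarts = 1,
                      seed = 3)
  Z <- deviationZScores(mod, m[te, ], pt[te, c("age", "sex")])
  expect_lt(abs(mean(Z)), 0.1)
  expect_gt(mean(apply(Z, 2, var)), 0.8)
  expect_lt(mean(apply(Z, 2, var)), 1.2)
  # region mismatch is caught
  m2 <- m[te, ]; colnames(m2)[1] <- "bogus"
  expect_error(deviationZScores(mod, m2, pt[te, c("age", "sex")]),
               "region ids")
})

test_that("cross-validation reports SMSE with the mean-prediction anchor", {
  co <- smallCohort()
  cv <- crossvalidateNormative(co, scheme = "kfold", nFolds = 4,
                               nRepeats = 1, nRestarts = 1, seed = 2,
                               predictor = "mean")
  expect_equal(unname(cv$perRegionSMSE),
               matrix(1, nrow(cv$perRegionSMSE), ncol(cv$perRegionSMSE)),
               tolerance = 1e-12)
  expect_error(
    crossvalidateNormative(gmvMatrix(co), participants(co), site = NULL,
                           scheme = "loso"),
    "loso requires")
})

test_that("extreme-deviation maps count strictly beyond the threshold", {
  Z <- matrix(0, 10, 4, dimnames = list(NULL, paste0("R", 1:4)))
  Z[1:3, 2] <- 2.5          # three extreme-positive subjects in region 2
  Z[7, 3] <- -2.5
  Z[9, 1] <- 1.96           # exactly at threshold: not extreme
  om <- extremeDeviationMaps(Z)
  expect_equal(unname(om$posPct), c(0, 30, 0, 0))
  expect_equal(om$pctAnyNeg, 10)
  expect_gte(om$pctAnyNeg, 1 / 10 * 100)
  expect_equal(om$maxOverlapPct, 30)
  # all sub-threshold -> zeros
  om0 <- extremeDeviationMaps(matrix(rnorm(40, 0, 0.1), 10, 4))
  expect_equal(max(om0$posPct, om0$negPct), 0)
  # monotone in the threshold
  set.seed(2)
  Zr <- matrix(rnorm(600), 30, 20)
  a <- extremeDeviationMaps(Zr, 1.5)
  b <- extremeDeviationMaps(Zr, 2.5)
  expect_true(all(b$posPct <= a$posPct))
  expect_true(all(b$negPct <= a$negPct))
  expect_lte(b$maxOverlapPct, a$maxOverlapPct)
  expect_error(extremeDeviationMaps(Zr, 0), "positive")
  expect_error(extremeDeviationMaps(matrix(0, 0, 0)), "non-empty")
})
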