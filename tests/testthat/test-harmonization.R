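siteCohort <- function(seed = 21, n = 100) {
  generateCohort(cohortConfig(nSites = 2, nHCPerSite = n, nPatPerSite = 1,
                              nRegions = 8, siteShiftSd = 1,
                              siteScaleRange = c(0.7, 1.4), seed = seed))
}

test_that("degenerate inputs are rejected", {
  m <- matrix(rnorm(60), 10, 6)
  expect_error(combatHarmonize(m, site = rep("a", 10)), "2 sites")
  expect_error(combatHarmonize(m, site = c(rep("a", 8), "b", "b")),
               "< 3 subjects")
  X <- cbind(x1 = rnorm(10), x2 = 0)
  X[, 2] <- 2 * X[, 1]
  expect_error(combatHarmonize(m, site = rep(c("a", "b"), each = 5),
                               covariates = X), "collinear")
})

test_that("planted site effects shrink by >= 90% in site-mean separation", {
  co <- siteCohort()
  pt <- participants(co)
  m <- gmvMatrix(co)
  harm <- combatHarmonize(co)
  m2 <- gmvMatrix(harm$experiment)
  sep <- function(M) mean(apply(M, 2, function(y)
    abs(diff(tapply(y, pt$site, mean)))))
  expect_lt(sep(m2), 0.1 * sep(m))
})

test_that("covariate effects survive harmonization", {
  # slope large enough that a 5% relative band sits well above the OLS
  # standard error at n = 400
  co <- generateCohort(cohortConfig(nSites = 4, nHCPerSite = 100,
                                    nPatPerSite = 1, nRegions = 8,
                                    betaAge = -0.1, siteShiftSd = 0.8,
                                    seed = 33))
  pt <- participants(co)
  truth <- groundTruth(co)
  harm <- combatHarmonize(co)
  m2 <- gmvMatrix(harm$experiment)
  slopes <- vapply(seq_len(ncol(m2)), function(g)
    coef(lm(m2[, g] ~ pt$age + pt$sex))["pt$age"], 0)
  # age slope recovered within 5% at n = 400
  expect_lt(max(abs(slopes - truth$betaAge) / abs(truth$betaAge)), 0.05)
})

test_that("fitted covariate effects agree before and after harmonization", {
  # heterogeneous slopes so the across-region correlation reflects the
  # effects, not estimation noise
  co <- generateCohort(cohortConfig(nSites = 4, nHCPerSite = 100,
                                    nPatPerSite = 1, nRegions = 8,
                                    betaAge = seq(-0.15, -0.05,
                                                  length.out = 8),
                                    siteShiftSd = 0.8, seed = 34))
  pt <- participants(co)
  harm <- combatHarmonize(co)
  m2 <- gmvMatrix(harm$experiment)
  post <- vapply(seq_len(ncol(m2)), function(g)
    coef(lm(m2[, g] ~ pt$age + pt$sex))["pt$age"], 0)
  pre <- vapply(seq_len(ncol(m2)), function(g)
    coef(lm(gmvMatrix(co)[, g] ~ pt$age + pt$sex +
              factor(pt$site)))["pt$age"], 0)
  expect_gt(cor(pre, post), 0.99)
})

test_that("harmonization reduces variance and is nearly idempotent", {
  co <- siteCohort(seed = 44)
  m <- gmvMatrix(co)
  pt <- participants(co)
  X <- cbind(age = pt$age, sex = pt$sex)
  h1 <- combatHarmonize(m, pt$site, X)
  expect_true(all(apply(h1$corrected, 2, var) <= apply(m, 2, var) + 1e-9))
  h2 <- combatHarmonize(h1$corrected, pt$site, X)
  rms <- sqrt(mean((h2$corrected - h1$corrected)^2)) /
    sqrt(mean(scale(h1$corrected, scale = FALSE)^2))
  expect_lt(rms, 0.01)
  # EB scale factors are positive and the model serializes
  expect_true(all(h1$model$siteScale > 0))
  tmp <- tempfile(fileext = ".json")
  writeCombatModel(h1$model, tmp)
  expect_true(jsonlite::validate(readLines(tmp, warn = FALSE) |>
                                   paste(collapse = "")))
})

test_that("output matches the reference ComBat implementation", {
  skip_if_not_installed("sva")
  co <- siteCohort(seed = 55, n = 40)
  pt <- participants(co)
  m <- gmvMatrix(co)
  X <- cbind(age = pt$age, sex = pt$sex)
  ours <- combatHarmonize(m, pt$site, X)$corrected
  ref <- t(sva::ComBat(dat = t(m), batch = pt$site,
                       mod = cbind(1, X), prior.plots = FALSE))
  expect_gt(cor(as.numeric(ours), as.numeric(ref)), 0.9999)
  expect_lt(max(abs(ours - ref)) / sd(m), 0.02)
})
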