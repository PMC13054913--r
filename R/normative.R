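#' Fit per-region Gaussian process normative models on healthy controls
#'
#' One GP per region models regional GMV as a smooth function of age and
#' sex in healthy controls (squared-exponential kernel with one
#' length-scale per predictor, plus white noise). Hyperparameters maximize
#' the marginal likelihood with multiple random restarts; covariates are
#' standardized to the training mean/SD.
#'
#' @param x a [GMVExperiment-class] (HC columns are selected by `group ==
#'   "HC"`) or a subjects x regions matrix of healthy controls only.
#' @param covariates for a matrix: data.frame with numeric `age` and `sex`
#'   coded 0/1, one row per subject.
#' @param nRestarts random restarts for hyperparameter optimization.
#' @param minHC minimum number of controls required.
#' @param seed integer seed (restart initialization).
#' @return a [NormativeModelSet-class].
#' @examples
#' cohort <- generateCohort(cohortConfig(nSites = 2, nHCPerSite = 15,
#'                                       nPatPerSite = 5, nRegions = 6,
#'                                       seed = 3))
#' models <- fitNormative(cohort, nRestarts = 1)
#' models
#' @export
setGeneric("fitNormative",
           function(x, covariates = NULL, nRestarts = 3L, minHC = 20L,
                    seed = 1L) standardGeneric("fitNormative"))

#' @rdname fitNormative
#' @export
setMethod("fitNormative", "GMVExperiment",
  function(x, covariates = NULL, nRestarts = 3L, minHC = 20L, seed = 1L) {
    pt <- participants(x)
    hc <- pt$group == "HC"
    fitNormative(gmvMatrix(x)[hc, , drop = FALSE],
                 pt[hc, c("age", "sex")], nRestarts, minHC, seed)
  })

#' @rdname fitNormative
#' @export
setMethod("fitNormative", "matrix",
  function(x, covariates, nRestarts = 3L, minHC = 20L, seed = 1L) {
    n <- nrow(x)
    if (n < minHC)
      stop("need >= ", minHC, " healthy controls, got ", n, call. = FALSE)
    if (!all(c("age", "sex") %in% colnames(covariates)))
      stop("covariates must contain 'age' and 'sex'")
    if (!all(covariates$sex %in% c(0, 1)))
      stop("sex must be coded 0/1")
    if (any(!is.finite(covariates$age))) stop("age must be finite")
    bad <- colnames(x)[colSums(!is.finite(x)) > 0]
    if (length(bad))
      stop("non-finite targets in region(s): ",
           paste(head(bad, 5), collapse = ", "))
    Xraw <- cbind(age = covariates$age, sex = covariates$sex)
    xCenter <- colMeans(Xraw)
    xScale <- apply(Xraw, 2, sd)
    xScale[xScale == 0] <- 1
    X <- sweep(sweep(Xraw, 2, xCenter), 2, xScale, "/")
    Dlist <- .sqDiffList(X)
    regionIds <- colnames(x)
    if (is.null(regionIds)) regionIds <- sprintf("R%03d", seq_len(ncol(x)))
    models <- vector("list", ncol(x))
    for (g in seq_len(ncol(x)))
      models[[g]] <- .gpFitRegion(Dlist, x[, g], nRestarts,
                                  seed = .childSeed(seed, regionIds[g]))
    names(models) <- regionIds
    methods::new("NormativeModelSet", models = models,
                 regionIds = regionIds,
                 covariateNames = c("age", "sex"),
                 xCenter = xCenter, xScale = xScale, Xtrain = X,
                 seed = as.integer(seed))
  })

setMethod("show", "NormativeModelSet", function(object) {
  cat("NormativeModelSet:", length(object@models), "regions,",
      nrow(object@Xtrain), "training controls; predictors:",
      paste(object@covariateNames, collapse = ", "), "\n")
  invisible(NULL)
})

#' @describeIn fitNormative hyperparameters and standardization constants
#'   as a data.frame (one row per region), suitable for JSON export.
#' @param models a `NormativeModelSet`.
#' @export
normativeHyperparameters <- function(models) {
  stopifnot(methods::is(models, "NormativeModelSet"))
  th <- t(vapply(models@models, function(m) m$theta,
                 numeric(length(models@models[[1]]$theta))))
  data.frame(region = models@regionIds, th,
             yMean = vapply(models@models, `[[`, 0, "yMean"),
             ySd = vapply(models@models, `[[`, 0, "ySd"),
             logLik = vapply(models@models, `[[`, 0, "logLik"),
             row.names = NULL)
}

# standardized covariates + cross squared-difference lists for prediction
.predGrid <- function(models, covariates) {
  Xraw <- cbind(age = covariates$age, sex = covariates$sex)
  Xnew <- sweep(sweep(Xraw, 2, models@xCenter), 2, models@xScale, "/")
  .sqDiffList(models@Xtrain, Xnew)
}

#' Individualized deviation Z-scores against the normative model
#'
#' For subject s and region g,
#' `Z = (y - mu) / sqrt(predVar + noiseVar)`, where `mu` and `predVar` are
#' the GP predictive mean and latent variance at the subject's covariates
#' and `noiseVar` is the fitted noise variance (so held-out controls are
#' calibrated to unit variance). Positive Z means higher GMV than the
#' normative expectation.
#'
#' @param models a [NormativeModelSet-class] fitted on controls.
#' @param x a [GMVExperiment-class] or a subjects x regions matrix; region
#'   ids must match the models.
#' @param covariates for a matrix: data.frame with `age` and `sex`.
#' @param patientsOnly for a `GMVExperiment`: restrict to non-HC subjects
#'   (default TRUE, the paper's patients x regions Z matrix).
#' @return subjects x regions numeric matrix of Z-scores.
#' @export
setGeneric("deviationZScores",
           function(models, x, covariates = NULL, patientsOnly = TRUE)
             standardGeneric("deviationZScores"))

#' @rdname deviationZScores
#' @export
setMethod("deviationZScores", signature("NormativeModelSet",
                                        "GMVExperiment"),
  function(models, x, covariates = NULL, patientsOnly = TRUE) {
    pt <- participants(x)
    keep <- if (patientsOnly) pt$group != "HC" else rep(TRUE, nrow(pt))
    deviationZScores(models, gmvMatrix(x)[keep, , drop = FALSE],
                     pt[keep, c("age", "sex")])
  })

#' @rdname deviationZScores
#' @export
setMethod("deviationZScores", signature("NormativeModelSet", "matrix"),
  function(models, x, covariates, patientsOnly = TRUE) {
    if (!identical(colnames(x), models@regionIds))
      stop("region ids of the matrix do not match the fitted models",
           call. = FALSE)
    if (nrow(covariates) != nrow(x))
      stop("covariates required for every subject")
    Dcross <- .predGrid(models, covariates)
    Z <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
    for (g in seq_along(models@models)) {
      pr <- .gpPredictRegion(models@models[[g]], Dcross, nrow(x))
      Z[, g] <- (x[, g] - pr$mean) / sqrt(pr$var + pr$noiseVar)
    }
    Z
  })

#' Cross-validate the normative model (k-fold or leave-one-site-out)
#'
#' Per region and fold, the standardized mean squared error is
#' `SMSE = sum((y - yhat)^2) / sum((y - mean(y_test))^2)` on the held-out
#' controls; predicting the test mean gives SMSE = 1 by construction.
#' K-fold partitions are stratified by site and redrawn independently for
#' every repeat.
#'
#' @param x a [GMVExperiment-class] (HCs are selected) or an HC-only
#'   subjects x regions matrix.
#' @param covariates,site for a matrix: per-subject covariates
#'   (`age`, `sex`) and site labels.
#' @param scheme `"kfold"` or `"loso"`.
#' @param nFolds folds for `"kfold"`.
#' @param nRepeats independent k-fold repetitions.
#' @param nRestarts,minHC,seed passed to the per-fold fits; folds whose
#'   training half falls below `minHC` are skipped with a warning recorded
#'   in the report.
#' @param predictor `"gp"` (the normative model) or `"mean"` (predict the
#'   held-out mean: the SMSE normalization anchor, giving SMSE = 1 on
#'   every region by construction).
#' @return a `CVReport` list: `scheme`, `perRegionSMSE` (region x
#'   fold-instance matrix), `meanSMSE`, `sdSMSE`, `skipped`.
#' @export
setGeneric("crossvalidateNormative",
           function(x, covariates = NULL, site = NULL,
                    scheme = c("kfold", "loso"), nFolds = 10L,
                    nRepeats = 100L, nRestarts = 2L, minHC = 20L,
                    seed = 1L, predictor = c("gp", "mean"))
             standardGeneric("crossvalidateNormative"))

#' @rdname crossvalidateNormative
#' @export
setMethod("crossvalidateNormative", "GMVExperiment",
  function(x, covariates = NULL, site = NULL, scheme = c("kfold", "loso"),
           nFolds = 10L, nRepeats = 100L, nRestarts = 2L, minHC = 20L,
           seed = 1L, predictor = c("gp", "mean")) {
    pt <- participants(x)
    hc <- pt$group == "HC"
    crossvalidateNormative(gmvMatrix(x)[hc, , drop = FALSE],
                           pt[hc, c("age", "sex")], pt$site[hc], scheme,
                           nFolds, nRepeats, nRestarts, minHC, seed,
                           predictor)
  })

#' @rdname crossvalidateNormative
#' @export
setMethod("crossvalidateNormative", "matrix",
  function(x, covariates, site = NULL, scheme = c("kfold", "loso"),
           nFolds = 10L, nRepeats = 100L, nRestarts = 2L, minHC = 20L,
           seed = 1L, predictor = c("gp", "mean")) {
    scheme <- match.arg(scheme)
    predictor <- match.arg(predictor)
    n <- nrow(x)
    folds <- list()
    if (scheme == "kfold") {
      set.seed(.childSeed(seed, "cvfolds"))
      for (r in seq_len(nRepeats)) {
        fid <- .stratifiedFolds(site, n, nFolds)
        for (f in seq_len(nFolds))
          folds[[length(folds) + 1L]] <- which(fid == f)
      }
    } else {
      if (is.null(site) || length(unique(site)) < 2)
        stop("loso requires site labels with >= 2 sites", call. = FALSE)
      for (s in unique(site))
        folds[[length(folds) + 1L]] <- which(site == s)
      names(folds) <- unique(site)
    }
    smse <- matrix(NA_real_, ncol(x), length(folds),
                   dimnames = list(colnames(x), names(folds)))
    skipped <- character(0)
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(n), test)
      if (length(train) < minHC) {
        skipped <- c(skipped, paste0("fold ", f, ": only ",
                                     length(train), " training controls"))
        warning("skipping fold ", f, ": training split below minHC")
        next
      }
      if (predictor == "mean") {
        for (g in seq_len(ncol(x))) {
          yt <- x[test, g]
          smse[g, f] <- sum((yt - mean(yt))^2) / sum((yt - mean(yt))^2)
        }
      } else {
        models <- fitNormative(x[train, , drop = FALSE],
                               covariates[train, , drop = FALSE],
                               nRestarts = nRestarts, minHC = minHC,
                               seed = .childSeed(seed, paste0("fold", f)))
        Dcross <- .predGrid(models, covariates[test, , drop = FALSE])
        for (g in seq_len(ncol(x))) {
          pr <- .gpPredictRegion(models@models[[g]], Dcross, length(test))
          yt <- x[test, g]
          smse[g, f] <- sum((yt - pr$mean)^2) / sum((yt - mean(yt))^2)
        }
      }
    }
    vals <- smse[, colSums(is.na(smse)) == 0, drop = FALSE]
    structure(list(scheme = scheme, nFolds = nFolds, nRepeats = nRepeats,
                   perRegionSMSE = smse,
                   meanSMSE = mean(vals), sdSMSE = sd(colMeans(vals)),
                   skipped = skipped),
              class = "CVReport")
  })

.stratifiedFolds <- function(site, n, nFolds) {
  fid <- integer(n)
  if (is.null(site)) site <- rep("all", n)
  for (s in unique(site)) {
    idx <- sample(which(site == s))
    fid[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fid
}

#' Extreme-deviation overlap maps
#'
#' Counts, per region, the percentage of subjects whose deviation exceeds
#' `+threshold` (or falls below `-threshold`), plus cohort-level
#' percentages of subjects with at least one extreme region. Values exactly
#' at the threshold are not extreme (strict inequality).
#'
#' @param Z subjects x regions deviation matrix.
#' @param threshold positive Z cutoff (default 1.96, the two-tailed 95%
#'   bound of the normative distribution).
#' @return list with `posPct`/`negPct` (per-region %), `pctAnyPos` /
#'   `pctAnyNeg` (% of subjects with >= 1 extreme region), and
#'   `maxOverlapPct` (largest single-region overlap in either direction).
#' @export
extremeDeviationMaps <- function(Z, threshold = 1.96) {
  if (!is.matrix(Z) || nrow(Z) == 0 || ncol(Z) == 0)
    stop("Z must be a non-empty subjects x regions matrix", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  pos <- Z > threshold
  neg <- Z < -threshold
  list(posPct = colMeans(pos) * 100,
       negPct = colMeans(neg) * 100,
       pctAnyPos = mean(rowSums(pos) > 0) * 100,
       pctAnyNeg = mean(rowSums(neg) > 0) * 100,
       maxOverlapPct = max(colMeans(pos), colMeans(neg)) * 100,
       threshold = threshold)
}
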