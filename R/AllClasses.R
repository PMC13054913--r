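#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats var sd cor coef dist lm.fit mad optim p.adjust pchisq
#'   pnorm pt qnorm quantile rbinom rnorm runif setNames t.test chisq.test
#'   ks.test kmeans model.matrix
#' @importFrom utils head combn read.delim write.table
NULL

#' Multi-site regional gray matter volume cohort
#'
#' `GMVExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] to hold a regions x
#' subjects gray matter volume (GMV) matrix together with per-subject
#' phenotypes. The assay named `"gmv"` stores regional volumes (regions as
#' rows, subjects as columns); `colData` must carry `participant_id`, `age`,
#' `sex` (0 = male, 1 = female), `site` and `group` (`"HC"` for healthy
#' controls, anything else for patients).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment-class].
#' @seealso [GMVExperiment()], [generateCohort()]
#' @export
setClass("GMVExperiment", contains = "SummarizedExperiment")

.validGMVExperiment <- function(object) {
  msg <- NULL
  if (!"gmv" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'gmv' is required")
  need <- c("participant_id", "age", "sex", "site", "group")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (is.null(msg)) {
    sex <- SummarizedExperiment::colData(object)$sex
    if (!all(sex %in% c(0, 1)))
      msg <- c(msg, "sex must be coded 0/1 (female = 1)")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("GMVExperiment", .validGMVExperiment)

#' Per-region Gaussian process normative models
#'
#' One Gaussian process regression model per brain region, fitted on healthy
#' controls with age and sex as predictors. Kernel: anisotropic squared
#' exponential (one length-scale per predictor) plus white noise;
#' hyperparameters are maximized marginal likelihood. Covariates are
#' standardized to the training mean/SD; targets are centered and scaled per
#' region (constants stored for prediction on the original scale).
#'
#' @slot models list of per-region fits (log-hyperparameters, cached
#'   Cholesky solves, target standardization constants, log marginal
#'   likelihood).
#' @slot regionIds character, region identifiers (one model each).
#' @slot covariateNames character, predictor names in training order.
#' @slot xCenter,xScale numeric, covariate standardization constants.
#' @slot Xtrain numeric matrix, standardized training covariates.
#' @slot seed integer seed used for restart initialization.
#' @seealso [fitNormative()], [deviationZScores()]
#' @export
setClass("NormativeModelSet",
  representation(models = "list", regionIds = "character",
                 covariateNames = "character", xCenter = "numeric",
                 xScale = "numeric", Xtrain = "matrix", seed = "integer"))

setValidity("NormativeModelSet", function(object) {
  if (length(object@models) != length(object@regionIds))
    return("one model per region required")
  noise <- vapply(object@models, function(m) exp(m$theta[["log_sn2"]]), 0)
  if (any(!is.finite(noise)) || any(noise <= 0))
    return("noise variance must be positive and finite")
  TRUE
})

#' Result of the SigClust cluster-existence test
#'
#' Tests the null hypothesis that the data arise from a single Gaussian
#' distribution using the 2-means cluster index (within-cluster sum of
#' squares of the best bipartition divided by total sum of squares) against
#' a simulated Gaussian null whose covariance eigenvalues are floored at a
#' robust background-noise variance estimate.
#'
#' @slot clusterIndex observed 2-means cluster index in (0, 1].
#' @slot nullDistribution simulated null cluster indices.
#' @slot pValue permutation-style p, `(1 + #\{null <= obs\}) / (nSim + 1)`.
#' @slot nSim number of null simulations.
#' @slot backgroundVariance robust noise-variance estimate
#'   `(MAD / 0.6745)^2`.
#' @slot eigenvalues floored covariance eigenvalues used for the null.
#' @seealso [sigClust()]
#' @export
setClass("SigClustResult",
  representation(clusterIndex = "numeric", nullDistribution = "numeric",
                 pValue = "numeric", nSim = "integer",
                 backgroundVariance = "numeric", eigenvalues = "numeric"))

setValidity("SigClustResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("p must lie in [0,1]")
  if (object@clusterIndex <= 0 || object@clusterIndex > 1)
    return("cluster index must lie in (0,1]")
  TRUE
})

#' Subtype solution from correlation-distance K-means with ensemble voting
#'
#' @slot labels integer cluster labels named by subject id.
#' @slot kSelected selected number of clusters (plurality of index votes;
#'   ties go to the smallest k).
#' @slot votes named integer, votes received by each candidate k.
#' @slot indexValues numeric matrix (k x index) of validity-index values.
#' @slot indexBest named integer, the k preferred by each index.
#' @slot totalDistance total within-cluster correlation distance at the
#'   selected k.
#' @slot nInit number of K-means restarts per k.
#' @slot seed integer seed.
#' @seealso [selectKEnsemble()], [kmeansCorrelation()]
#' @export
setClass("SubtypeResult",
  representation(labels = "integer", kSelected = "integer",
                 votes = "integer", indexValues = "matrix",
                 indexBest = "integer", totalDistance = "numeric",
                 nInit = "integer", seed = "integer"))

setValidity("SubtypeResult", function(object) {
  if (any(is.na(object@labels))) return("labels must cover all subjects")
  if (length(object@votes) && sum(object@votes) != length(object@indexBest))
    return("votes must sum to the number of voting indices")
  TRUE
})

#' Regional neurotransmitter receptor/transporter density maps
#'
#' Regions x receptors density matrix, Z-scored across regions per
#' receptor, with an excitatory/inhibitory class label (and optionally a
#' neurotransmitter-system label) per receptor.
#'
#' @slot densities numeric matrix, regions x receptors (Z-scored columns).
#' @slot receptorClass named character, `"excitatory"` or `"inhibitory"`.
#' @slot system named character, neurotransmitter system per receptor.
#' @seealso [ReceptorAtlas()], [receptorModelFit()], [dominanceAnalysis()]
#' @export
setClass("ReceptorAtlas",
  representation(densities = "matrix", receptorClass = "character",
                 system = "character"))

setValidity("ReceptorAtlas", function(object) {
  d <- object@densities
  if (is.null(colnames(d))) return("receptor columns must be named")
  mu <- colMeans(d); s <- apply(d, 2, sd)
  if (any(abs(mu) > 1e-8) || any(abs(s - 1) > 1e-8))
    return("densities must be Z-scored per receptor (mean 0, SD 1)")
  if (!all(names(object@receptorClass) == colnames(d)))
    return("receptorClass names must match receptor columns")
  if (!all(object@receptorClass %in% c("excitatory", "inhibitory")))
    return("receptor classes must be 'excitatory' or 'inhibitory'")
  TRUE
})

#' Dominance analysis of a multilinear receptor model
#'
#' Decomposes the full-model R^2 into per-predictor total dominance values:
#' the average increase in explained variance when a predictor joins a
#' sub-model, averaged over all sub-model sizes. Total dominance values sum
#' to the full-model R^2.
#'
#' @slot fullR2,adjustedR2 full-model fit.
#' @slot totalDominance named numeric, per-predictor total dominance.
#' @slot relativeDominance named numeric, shares of the full R^2.
#' @slot conditional numeric matrix (predictor x sub-model size) of
#'   conditional dominance values.
#' @slot permutationP permutation p for the full model (NA when not run).
#' @slot nPermutations number of permutations used.
#' @seealso [dominanceAnalysis()], [classContribution()]
#' @export
setClass("DominanceResult",
  representation(fullR2 = "numeric", adjustedR2 = "numeric",
                 totalDominance = "numeric", relativeDominance = "numeric",
                 conditional = "matrix", permutationP = "numeric",
                 nPermutations = "integer"))

setValidity("DominanceResult", function(object) {
  if (abs(sum(object@totalDominance) - object@fullR2) > 1e-8)
    return("total dominance must sum to the full-model R^2")
  TRUE
})

#' Disease-epicenter likelihood ranking
#'
#' Regions ranked jointly by their own abnormality and by their
#' transcriptomic neighbors' abnormality; the mean of the two ranks is the
#' epicenter likelihood, tested against a permutation null obtained by
#' shuffling the abnormality map over regions.
#'
#' @slot table data.frame with `region`, `d`, `dTilde`, `ownRank`,
#'   `neighborRank`, `meanRank`, `p`, `isEpicenter`.
#' @slot direction `"ascending"` (most negative abnormality ranks first) or
#'   `"descending"`.
#' @slot alpha significance level for epicenter designation.
#' @slot nPerm number of permutations.
#' @slot undefinedRegions regions with no positive transcriptomic
#'   connections, excluded from ranking.
#' @seealso [epicenterTest()], [neighborDeviation()]
#' @export
setClass("EpicenterResult",
  representation(table = "data.frame", direction = "character",
                 alpha = "numeric", nPerm = "integer",
                 undefinedRegions = "character"))
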