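#' Harmonize multi-site data with parametric empirical-Bayes ComBat
#'
#' Removes additive (location) and multiplicative (scale) site effects from
#' a subjects x regions matrix while preserving the specified biological
#' covariates. Per region, the model `y = alpha + X beta + gamma_site +
#' delta_site * eps` is fitted; standardized site parameters are shrunk
#' toward parametric priors (normal for locations, inverse-gamma for
#' variances) by the empirical-Bayes iteration, and data are reconstructed
#' without the site terms.
#'
#' @param x a [GMVExperiment-class] or a subjects x regions numeric
#'   matrix.
#' @param site per-subject site labels (ignored for `GMVExperiment`, which
#'   carries them). At least 2 sites with >= 3 subjects each.
#' @param covariates for a matrix: numeric design matrix / data.frame of
#'   covariates to protect (no intercept column); for a `GMVExperiment`:
#'   character vector of `colData` columns (default age, sex and the
#'   patient/control indicator so diagnosis signal is not removed).
#' @param tol convergence tolerance on successive EB estimates.
#' @param maxIter iteration cap.
#' @return for a matrix: list with `corrected` (harmonized matrix) and
#'   `model` (a `CombatModel` list: grand effects, EB-shrunk site
#'   location/scale, pooled SDs, prior hyperparameters). For a
#'   `GMVExperiment`: list with `experiment` (harmonized) and `model`.
#' @examples
#' cohort <- generateCohort(cohortConfig(nSites = 3, nHCPerSite = 20,
#'                                       nPatPerSite = 10, nRegions = 10,
#'                                       seed = 2))
#' harm <- combatHarmonize(cohort)
#' harm$model$iterations
#' @export
setGeneric("combatHarmonize",
           function(x, site = NULL, covariates = NULL, tol = 1e-4,
                    maxIter = 500L) standardGeneric("combatHarmonize"))

#' @rdname combatHarmonize
#' @export
setMethod("combatHarmonize", "matrix",
  function(x, site, covariates = NULL, tol = 1e-4, maxIter = 500L) {
    .combatCore(x, site, covariates, tol, maxIter)
  })

#' @rdname combatHarmonize
#' @export
setMethod("combatHarmonize", "GMVExperiment",
  function(x, site = NULL, covariates = c("age", "sex", "group"),
           tol = 1e-4, maxIter = 500L) {
    pt <- participants(x)
    X <- .covariateDesign(pt, covariates)
    res <- .combatCore(gmvMatrix(x), pt$site, X, tol, maxIter)
    corrected <- GMVExperiment(res$corrected, pt,
                               metadata = S4Vectors::metadata(x))
    list(experiment = corrected, model = res$model)
  })

# numeric design (no intercept) from participants columns; factors and
# characters are dummy-coded
.covariateDesign <- function(pt, covariates) {
  if (is.null(covariates) || !length(covariates)) return(NULL)
  miss <- setdiff(covariates, colnames(pt))
  if (length(miss)) stop("unknown covariate column(s): ",
                         paste(miss, collapse = ", "))
  df <- pt[, covariates, drop = FALSE]
  for (v in colnames(df)) if (is.character(df[[v]]))
    df[[v]] <- factor(df[[v]])
  X <- model.matrix(~ ., data = df)[, -1, drop = FALSE]
  X
}

.combatCore <- function(Y, site, covariates, tol = 1e-4, maxIter = 500L) {
  Y <- as.matrix(Y)
  site <- factor(site)
  if (nlevels(site) < 2)
    stop("need >= 2 sites; nothing to harmonize", call. = FALSE)
  nPer <- table(site)
  if (any(nPer < 3))
    stop("site(s) with < 3 subjects: ",
         paste(names(nPer)[nPer < 3], collapse = ", "), call. = FALSE)
  n <- nrow(Y); G <- ncol(Y); B <- nlevels(site)

  batchDesign <- model.matrix(~ site - 1)
  colnames(batchDesign) <- levels(site)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  design <- if (is.null(X)) batchDesign else cbind(batchDesign, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design is singular; collinear column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }

  Bhat <- solve(crossprod(design), crossprod(design, Y))
  nFrac <- as.numeric(nPer) / n
  alpha <- drop(nFrac %*% Bhat[seq_len(B), , drop = FALSE])
  standMean <- matrix(alpha, n, G, byrow = TRUE)
  if (!is.null(X))
    standMean <- standMean +
      X %*% Bhat[-seq_len(B), , drop = FALSE]
  varPooled <- colMeans((Y - design %*% Bhat)^2)
  if (any(varPooled <= 0))
    stop("region(s) with zero residual variance", call. = FALSE)
  sdPooled <- sqrt(varPooled)
  Z <- (Y - standMean) / matrix(sdPooled, n, G, byrow = TRUE)

  gammaHat <- deltaHat <- matrix(0, B, G,
                                 dimnames = list(levels(site), colnames(Y)))
  for (b in seq_len(B)) {
    rows <- site == levels(site)[b]
    gammaHat[b, ] <- colMeans(Z[rows, , drop = FALSE])
    deltaHat[b, ] <- apply(Z[rows, , drop = FALSE], 2, var)
  }
  gammaBar <- rowMeans(gammaHat)
  tau2 <- apply(gammaHat, 1, var)
  dMean <- rowMeans(deltaHat)
  dVar <- apply(deltaHat, 1, var)
  aPrior <- (2 * dVar + dMean^2) / dVar
  bPrior <- (dMean * dVar + dMean^3) / dVar

  gammaStar <- gammaHat
  delta2Star <- deltaHat
  iters <- integer(B)
  for (b in seq_len(B)) {
    rows <- site == levels(site)[b]
    nb <- sum(rows)
    Zb <- Z[rows, , drop = FALSE]
    gOld <- gammaHat[b, ]; dOld <- deltaHat[b, ]
    for (it in seq_len(maxIter)) {
      gNew <- (nb * tau2[b] * gammaHat[b, ] + dOld * gammaBar[b]) /
        (nb * tau2[b] + dOld)
      sum2 <- colSums((Zb - matrix(gNew, nb, G, byrow = TRUE))^2)
      dNew <- (0.5 * sum2 + bPrior[b]) / (nb / 2 + aPrior[b] - 1)
      change <- max(abs(gNew - gOld) / pmax(abs(gOld), 1e-12),
                    abs(dNew - dOld) / pmax(abs(dOld), 1e-12))
      gOld <- gNew; dOld <- dNew
      if (change < tol) break
    }
    iters[b] <- it
    gammaStar[b, ] <- gOld
    delta2Star[b, ] <- dOld
  }

  idx <- as.integer(site)
  corrected <- (Z - gammaStar[idx, , drop = FALSE]) /
    sqrt(delta2Star[idx, , drop = FALSE]) *
    matrix(sdPooled, n, G, byrow = TRUE) + standMean
  dimnames(corrected) <- dimnames(Y)

  model <- list(
    sites = levels(site),
    grandEffects = list(alpha = alpha,
                        beta = if (is.null(X)) NULL
                               else Bhat[-seq_len(B), , drop = FALSE]),
    siteLocation = gammaStar,
    siteScale = delta2Star,
    pooledSd = sdPooled,
    priorParams = list(gammaBar = gammaBar, tau2 = tau2,
                       aPrior = aPrior, bPrior = bPrior),
    iterations = setNames(iters, levels(site)),
    covariateNames = if (is.null(X)) character(0) else colnames(X))
  class(model) <- "CombatModel"
  list(corrected = corrected, model = model)
}

#' Serialize a CombatModel to JSON for audit
#'
#' @param model a `CombatModel` from [combatHarmonize()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeCombatModel <- function(model, path) {
  stopifnot(inherits(model, "CombatModel"))
  out <- model
  class(out) <- NULL
  out$siteLocation <- as.data.frame(out$siteLocation)
  out$siteScale <- as.data.frame(out$siteScale)
  .writeJSON(out, path)
}
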