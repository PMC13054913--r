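#' SigClust test for the existence of cluster structure
#'
#' Tests the null hypothesis that the rows of `X` are draws from a single
#' multivariate Gaussian. The statistic is the 2-means cluster index
#' (within-cluster sum of squares of the best bipartition divided by the
#' total sum of squares about the grand mean). The null distribution is
#' simulated from Gaussians with diagonal covariance given by the sample
#' covariance eigenvalues floored at a robust background-noise variance,
#' `(MAD of all entries / 0.6745)^2`; the cluster index is rotation
#' invariant, so simulating in the eigenbasis is exact.
#'
#' @param X subjects x features matrix (e.g. a deviation Z matrix).
#' @param nSim null simulations (a warning is issued below 100).
#' @param nStart K-means restarts used for both the observed and the null
#'   cluster indices.
#' @param seed integer seed.
#' @return a [SigClustResult-class].
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(200), 20), matrix(rnorm(200, 4), 20))
#' sigClust(X, nSim = 99, seed = 1)
#' @export
sigClust <- function(X, nSim = 1000L, nStart = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("need >= 10 subjects", call. = FALSE)
  if (sd(as.numeric(X)) == 0)
    stop("constant matrix: cluster index undefined", call. = FALSE)
  nSim <- .assertCount(nSim, "nSim")
  if (nSim < 100) warning("nSim < 100 gives an unstable p-value")
  set.seed(.childSeed(seed, "sigclust"))

  obs <- .clusterIndex(X, nStart)
  sigma2b <- mad(as.numeric(X))^2    # mad() scales by 1/0.6745
  # population-spectrum estimate: raw sample eigenvalues are spread by
  # Wishart sampling noise, which would make the simulated null more
  # elongated than the data themselves (a badly conservative test at
  # moderate p/n); linear (Ledoit-Wolf) shrinkage toward the spherical
  # target undoes that spread before the background-variance floor
  ev <- .shrunkEigenvalues(X)
  ev <- pmax(ev, sigma2b)
  sdv <- sqrt(ev)
  nullCI <- vapply(seq_len(nSim), function(i) {
    sim <- matrix(rnorm(n * p), n, p) %*% diag(sdv, p)
    .clusterIndex(sim, nStart)
  }, 0)
  p <- .permP(nullCI, obs, side = "le")
  methods::new("SigClustResult", clusterIndex = obs,
               nullDistribution = nullCI, pValue = p,
               nSim = as.integer(nSim), backgroundVariance = sigma2b,
               eigenvalues = ev)
}

# Ledoit-Wolf linear shrinkage of the covariance toward m*I; returns the
# eigenvalues of the shrunk estimate
.shrunkEigenvalues <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2) / p
  b2bar <- 0
  for (i in seq_len(n)) {
    xi <- Xc[i, ]
    b2bar <- b2bar + sum((tcrossprod(xi) - S)^2)
  }
  b2bar <- b2bar / (n^2 * p)
  b2 <- min(b2bar, d2)
  rho <- b2 / d2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  rho * m + (1 - rho) * ev * n / (n - 1)
}

# 2-means cluster index: best within-SS over restarts / total SS
.clusterIndex <- function(X, nStart) {
  tss <- sum(sweep(X, 2, colMeans(X))^2)
  km <- kmeans(X, centers = 2, nstart = nStart, iter.max = 50)
  km$tot.withinss / tss
}

setMethod("show", "SigClustResult", function(object) {
  cat("SigClust: cluster index =", round(object@clusterIndex, 4),
      "| p =", signif(object@pValue, 4),
      paste0("(", object@nSim, " null simulations)\n"))
  cat("  background variance =", signif(object@backgroundVariance, 4),
      "| eigenvalues floored:", sum(object@eigenvalues ==
                                      object@backgroundVariance), "\n")
  invisible(NULL)
})

#' @describeIn sigClust p-value accessor.
#' @param object a `SigClustResult`.
#' @export
sigClustP <- function(object) object@pValue
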