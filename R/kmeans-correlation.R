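#' Correlation distance between row profiles
#'
#' `1 - cor` between all row pairs, the metric used for subtyping (two
#' subjects are close when their regional deviation profiles are
#' proportional, regardless of overall magnitude).
#'
#' @param X subjects x features matrix (no constant rows).
#' @return symmetric n x n distance matrix with zero diagonal; a row and
#'   its negation are at distance 2.
#' @export
correlationDistance <- function(X) {
  V <- .rowStandardize(as.matrix(X))
  D <- 1 - tcrossprod(V)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' K-means clustering under the correlation distance
#'
#' Rows are centered and scaled to unit norm, so the correlation between a
#' subject and a (re-centered, re-normalized) centroid is their dot
#' product and the correlation distance is `1 - dot`. Lloyd iterations
#' alternate nearest-centroid assignment with centroid re-estimation
#' (mean of assigned rows, re-normalized); the total within-cluster
#' correlation distance is non-increasing across iterations and the best
#' of `nInit` random restarts is returned. An empty cluster is reseeded at
#' the point farthest from its current centroid.
#'
#' @param X subjects x features matrix (no constant rows).
#' @param k number of clusters (2 <= k <= n).
#' @param nInit random restarts.
#' @param maxIter Lloyd iteration cap per restart.
#' @param seed integer seed.
#' @return list with `labels` (named integer), `centroids` (k x features,
#'   unit-norm rows), `totalDistance`, and `trace` (objective per
#'   iteration of the winning restart).
#' @examples
#' X <- rbind(matrix(rnorm(60, 2), 6), matrix(rnorm(60, -2), 6))
#' kmeansCorrelation(X, 2, nInit = 10, seed = 1)$labels
#' @export
kmeansCorrelation <- function(X, k, nInit = 100L, maxIter = 100L,
                              seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- .assertCount(k, "k", min = 2L)
  if (k > n) stop("k exceeds the number of subjects", call. = FALSE)
  V <- .rowStandardize(X)
  set.seed(.childSeed(seed, "kmeanscorr"))
  best <- NULL
  for (r in seq_len(nInit)) {
    res <- .lloydCorrelation(V, k, maxIter)
    if (is.null(best) || res$totalDistance < best$totalDistance)
      best <- res
  }
  # objective must not increase across Lloyd iterations
  stopifnot(all(diff(best$trace) <= 1e-8))
  names(best$labels) <- rownames(X)
  best
}

.lloydCorrelation <- function(V, k, maxIter) {
  n <- nrow(V)
  C <- V[sample(n, k), , drop = FALSE]
  labels <- integer(n)
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    S <- tcrossprod(V, C)                  # n x k correlations
    labels <- max.col(S, ties.method = "first")
    # reseed empty clusters at the point farthest from its centroid;
    # reseeding restarts the monotone objective segment
    empty <- which(tabulate(labels, k) == 0)
    if (length(empty)) {
      for (j in empty) {
        far <- which.max(1 - S[cbind(seq_len(n), labels)])
        labels[far] <- j
        S[far, ] <- 2                      # keep it assigned to j
        S[far, j] <- 2 + 1e-9
      }
      trace <- numeric(0)
    }
    Cnew <- matrix(0, k, ncol(V))
    for (j in seq_len(k)) {
      cj <- colSums(V[labels == j, , drop = FALSE])
      nrm <- sqrt(sum(cj^2))
      Cnew[j, ] <- if (nrm > 0) cj / nrm else V[sample(n, 1), ]
    }
    # objective after the update step, given the current labels
    obj <- sum(1 - tcrossprod(V, Cnew)[cbind(seq_len(n), labels)])
    trace <- c(trace, obj)
    if (max(abs(Cnew - C)) < 1e-10) { C <- Cnew; break }
    C <- Cnew
  }
  S <- tcrossprod(V, C)
  labels <- max.col(S, ties.method = "first")
  total <- sum(1 - S[cbind(seq_len(n), labels)])
  trace <- c(trace, total)
  list(labels = labels, centroids = C, totalDistance = total,
       trace = trace)
}
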