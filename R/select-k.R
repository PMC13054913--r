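#' Choose the number of subtypes by cluster-validity ensemble voting
#'
#' Correlation-distance K-means solutions are computed for every candidate
#' k; each cluster validity index then votes for the k it prefers under
#' its own rule (maximize or minimize, or the gap-statistic
#' one-standard-error rule), and the plurality wins, with ties broken
#' toward the smallest k. The default ensemble has nine indices:
#' silhouette, Calinski-Harabasz, Davies-Bouldin, Dunn, C-index, gap, PBM,
#' McClain-Rao and point-biserial; the set is pluggable.
#'
#' @param X subjects x features matrix (no constant rows).
#' @param kRange candidate cluster numbers (default 2:10).
#' @param indices character subset of
#'   `c("silhouette","ch","db","dunn","cindex","gap","pbm",
#'      "mcclain","pointbiserial")`; >= 3 (odd recommended).
#' @param nInit K-means restarts per k.
#' @param gapB reference datasets for the gap statistic.
#' @param seed integer seed.
#' @return a [SubtypeResult-class] with the labels of the winning k.
#' @examples
#' X <- rbind(matrix(rnorm(150, 3), 15), matrix(rnorm(150, -3), 15))
#' res <- selectKEnsemble(X, kRange = 2:4, nInit = 10, seed = 1)
#' kSelected(res)
#' @export
selectKEnsemble <- function(X, kRange = 2:10,
                            indices = c("silhouette", "ch", "db", "dunn",
                                        "cindex", "gap", "pbm", "mcclain",
                                        "pointbiserial"),
                            nInit = 100L, gapB = 10L, seed = 1L) {
  X <- as.matrix(X)
  indices <- match.arg(indices, several.ok = TRUE)
  if (length(indices) < 3)
    stop("need >= 3 validity indices for a meaningful vote")
  kRange <- sort(unique(as.integer(kRange)))
  if (min(kRange) < 2) stop("kRange must start at 2")
  V <- .rowStandardize(X)
  D <- 1 - tcrossprod(V)
  D[D < 0] <- 0; diag(D) <- 0

  sols <- lapply(kRange, function(k)
    kmeansCorrelation(X, k, nInit = nInit,
                      seed = .childSeed(seed, paste0("k", k))))
  names(sols) <- as.character(kRange)

  vals <- matrix(NA_real_, length(kRange), length(indices),
                 dimnames = list(as.character(kRange), indices))
  for (i in seq_along(kRange)) {
    lab <- sols[[i]]$labels
    for (ind in setdiff(indices, "gap")) {
      vals[i, ind] <- tryCatch(
        .validityIndex(ind, V, D, lab, kRange[i]),
        error = function(e) NA_real_)
    }
  }
  gapStats <- NULL
  if ("gap" %in% indices) {
    gapStats <- tryCatch(
      .gapStatistic(V, kRange, sols, B = gapB,
                    seed = .childSeed(seed, "gap")),
      error = function(e) NULL)
    if (!is.null(gapStats)) vals[, "gap"] <- gapStats$gap
  }

  bigger <- c(silhouette = TRUE, ch = TRUE, db = FALSE, dunn = TRUE,
              cindex = FALSE, gap = NA, pbm = TRUE, mcclain = FALSE,
              pointbiserial = TRUE)
  best <- setNames(rep(NA_integer_, length(indices)), indices)
  for (ind in indices) {
    v <- vals[, ind]
    if (all(is.na(v))) next                     # index abstains
    if (ind == "gap") {
      best[ind] <- .gapRule(gapStats, kRange)
    } else {
      best[ind] <- kRange[if (bigger[ind]) which.max(v) else which.min(v)]
    }
  }
  best <- best[!is.na(best)]
  votes <- table(factor(best, levels = kRange))
  top <- max(votes)
  kSel <- kRange[which(votes == top)[1]]        # tie -> smallest k

  win <- sols[[as.character(kSel)]]
  methods::new("SubtypeResult",
               labels = setNames(as.integer(win$labels),
                                 names(win$labels)),
               kSelected = as.integer(kSel),
               votes = setNames(as.integer(votes), names(votes)),
               indexValues = vals, indexBest = best,
               totalDistance = win$totalDistance,
               nInit = as.integer(nInit), seed = as.integer(seed))
}

#' @describeIn selectKEnsemble selected number of clusters.
#' @param object a `SubtypeResult`.
#' @export
kSelected <- function(object) object@kSelected

#' @describeIn selectKEnsemble named integer cluster labels.
#' @export
subtypeLabels <- function(object) object@labels

#' @describeIn selectKEnsemble votes per candidate k.
#' @export
ensembleVotes <- function(object) object@votes

setMethod("show", "SubtypeResult", function(object) {
  sizes <- table(object@labels)
  cat("SubtypeResult: k =", object@kSelected, "( sizes:",
      paste(sizes, collapse = " / "), ")\n")
  cat("  votes:", paste(names(object@votes), object@votes, sep = "=",
                        collapse = "  "), "\n")
  cat("  total correlation distance:",
      round(object@totalDistance, 3), "\n")
  invisible(NULL)
})

# ---- individual validity indices ---------------------------------------
# V: row-standardized data (dot product = correlation); D: correlation
# distance matrix; Euclidean geometry in V-space is used where an index
# needs centroids (||u - v||^2 = 2 * correlation distance there).

.validityIndex <- function(name, V, D, labels, k) {
  switch(name,
    silhouette = {
      sil <- cluster::silhouette(labels, dmatrix = D)
      mean(sil[, "sil_width"])
    },
    ch = .chIndex(V, labels, k),
    db = .dbIndex(V, labels, k),
    dunn = .dunnIndex(D, labels),
    cindex = .cIndex(D, labels),
    pbm = .pbmIndex(V, labels, k),
    mcclain = .mcclainRao(D, labels),
    pointbiserial = .pointBiserial(D, labels),
    stop("unknown index ", name))
}

.clusterMeans <- function(V, labels, k) {
  M <- matrix(0, k, ncol(V))
  for (j in seq_len(k)) M[j, ] <- colMeans(V[labels == j, , drop = FALSE])
  M
}

.chIndex <- function(V, labels, k) {
  n <- nrow(V)
  M <- .clusterMeans(V, labels, k)
  grand <- colMeans(V)
  W <- sum((V - M[labels, , drop = FALSE])^2)
  B <- sum(tabulate(labels, k) * rowSums(sweep(M, 2, grand)^2))
  (B / (k - 1)) / (W / (n - k))
}

.dbIndex <- function(V, labels, k) {
  M <- .clusterMeans(V, labels, k)
  s <- vapply(seq_len(k), function(j)
    mean(sqrt(rowSums((V[labels == j, , drop = FALSE] -
                         matrix(M[j, ], sum(labels == j), ncol(V),
                                byrow = TRUE))^2))), 0)
  Dm <- as.matrix(dist(M))
  r <- vapply(seq_len(k), function(j) {
    max(vapply(setdiff(seq_len(k), j),
               function(l) (s[j] + s[l]) / Dm[j, l], 0))
  }, 0)
  mean(r)
}

.dunnIndex <- function(D, labels) {
  k <- max(labels)
  within <- max(vapply(seq_len(k), function(j) {
    d <- D[labels == j, labels == j, drop = FALSE]
    if (length(d) == 1) 0 else max(d)
  }, 0))
  between <- min(vapply(seq_len(k - 1), function(j) {
    min(vapply((j + 1):k, function(l)
      min(D[labels == j, labels == l, drop = FALSE]), 0))
  }, 0))
  if (within == 0) return(Inf)
  between / within
}

.cIndex <- function(D, labels) {
  ut <- upper.tri(D)
  same <- outer(labels, labels, "==")[ut]
  dvec <- D[ut]
  nw <- sum(same)
  S <- sum(dvec[same])
  srt <- sort(dvec)
  Smin <- sum(srt[seq_len(nw)])
  Smax <- sum(srt[(length(srt) - nw + 1):length(srt)])
  (S - Smin) / (Smax - Smin)
}

.pbmIndex <- function(V, labels, k) {
  M <- .clusterMeans(V, labels, k)
  grand <- colMeans(V)
  E1 <- sum(sqrt(rowSums(sweep(V, 2, grand)^2)))
  Ek <- sum(sqrt(rowSums((V - M[labels, , drop = FALSE])^2)))
  Dk <- max(dist(M))
  ((E1 * Dk) / (Ek * k))^2
}

.mcclainRao <- function(D, labels) {
  ut <- upper.tri(D)
  same <- outer(labels, labels, "==")[ut]
  dvec <- D[ut]
  mean(dvec[same]) / mean(dvec[!same])
}

.pointBiserial <- function(D, labels) {
  ut <- upper.tri(D)
  same <- outer(labels, labels, "==")[ut]
  dvec <- D[ut]
  nt <- length(dvec); nw <- sum(same); nb <- nt - nw
  (mean(dvec[!same]) - mean(dvec[same])) *
    sqrt(nw * nb / nt^2) / sd(dvec)
}

# gap statistic: uniform reference draws over the bounding box of the
# row-standardized data, clustered with the same correlation K-means
.gapStatistic <- function(V, kRange, sols, B = 10L, seed = 1L) {
  set.seed(seed)
  n <- nrow(V); p <- ncol(V)
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  logWref <- matrix(NA_real_, B, length(kRange))
  for (b in seq_len(B)) {
    R <- matrix(runif(n * p), n, p)
    R <- sweep(sweep(R, 2, hi - lo, "*"), 2, lo, "+")
    for (i in seq_along(kRange)) {
      km <- kmeansCorrelation(R, kRange[i], nInit = 5L,
                              seed = seed + b * 131L + i)
      logWref[b, i] <- log(max(km$totalDistance, 1e-12))
    }
  }
  logW <- log(pmax(vapply(sols, `[[`, 0, "totalDistance"), 1e-12))
  gap <- colMeans(logWref) - logW
  sk <- apply(logWref, 2, sd) * sqrt(1 + 1 / B)
  list(gap = gap, sk = sk)
}

# Tibshirani one-standard-error rule; falls back to the max gap
.gapRule <- function(gapStats, kRange) {
  if (is.null(gapStats)) return(NA_integer_)
  g <- gapStats$gap; s <- gapStats$sk
  for (i in seq_len(length(kRange) - 1))
    if (g[i] >= g[i + 1] - s[i + 1]) return(kRange[i])
  kRange[which.max(g)]
}
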