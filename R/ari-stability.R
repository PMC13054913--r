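#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement, computed from the contingency
#' table: `ARI = (sum_ij C(n_ij,2) - E) / (0.5*(a + b) - E)` with
#' `a = sum_i C(a_i,2)`, `b = sum_j C(b_j,2)` and
#' `E = a*b / C(n,2)`. Invariant to label renaming; 1 for identical
#' partitions, ~0 for independent ones.
#'
#' @param a,b label vectors over the same subjects.
#' @return a single number in `[-1, 1]`.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(0)   # degenerate (e.g. all singletons)
  (sumij - expected) / (maxidx - expected)
}

#' Align cluster labels of one partition onto another
#'
#' Solves the assignment problem on the confusion matrix (maximum
#' agreement). Exact search over label permutations is used for k <= 8; a
#' greedy matching takes over for larger k.
#'
#' @param labels labels to be relabeled.
#' @param reference target labeling over the same subjects.
#' @return integer labels expressed in the reference's label ids.
#' @export
alignClusterLabels <- function(labels, reference) {
  if (length(labels) != length(reference))
    stop("label vectors differ in length", call. = FALSE)
  la <- as.integer(factor(labels))
  lb <- as.integer(factor(reference))
  ka <- max(la); kb <- max(lb)
  conf <- matrix(0L, ka, kb)
  for (i in seq_along(la)) conf[la[i], lb[i]] <- conf[la[i], lb[i]] + 1L
  if (ka <= 8 && kb <= 8) {
    # exact: permute the smaller side
    if (ka <= kb) {
      perms <- .permutations(kb)
      bestScore <- -1L; bestMap <- seq_len(ka)
      for (p in perms) {
        sc <- sum(conf[cbind(seq_len(ka), p[seq_len(ka)])])
        if (sc > bestScore) { bestScore <- sc; bestMap <- p[seq_len(ka)] }
      }
      map <- bestMap
    } else {
      map <- integer(ka)
      used <- logical(kb)
      # more source than target clusters: greedy on the exact leftovers
      ord <- order(-apply(conf, 1, max))
      for (i in ord) {
        j <- order(-conf[i, ])
        j <- j[!used[j]]
        if (length(j)) { map[i] <- j[1]; used[j[1]] <- TRUE }
        else map[i] <- which.max(conf[i, ])
      }
    }
  } else {
    map <- integer(ka)
    used <- logical(kb)
    for (i in order(-apply(conf, 1, max))) {
      j <- order(-conf[i, ])
      jf <- j[!used[j]]
      if (length(jf)) { map[i] <- jf[1]; used[jf[1]] <- TRUE }
      else map[i] <- j[1]
    }
  }
  lev <- sort(unique(reference))
  out <- lev[map[la]]
  if (is.integer(reference)) out <- as.integer(out)
  out
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- .permutations(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) for (pos in seq_len(k)) {
    out[[idx]] <- append(p, k, after = pos - 1L)
    idx <- idx + 1L
  }
  out
}

#' Clustering stability by subsampling or leave-one-site-out
#'
#' Subsample mode: `reps` independent draws of `floor(frac * N)` subjects
#' are re-clustered at the reference k, and each solution is compared to
#' the reference labels restricted to the drawn subjects via the adjusted
#' Rand index. LOSO mode: one site is removed at a time and the retained
#' subjects are re-clustered and compared likewise.
#'
#' @param X subjects x features matrix used for the reference clustering.
#' @param referenceLabels named or positional labels from the full-sample
#'   solution.
#' @param mode `"subsample"` or `"loso"`.
#' @param k number of clusters (defaults to the number of distinct
#'   reference labels).
#' @param frac subsample fraction in (0, 1).
#' @param reps subsample repetitions.
#' @param sites per-subject site labels (required for `"loso"`).
#' @param nInit K-means restarts per re-clustering.
#' @param seed integer seed.
#' @return a `StabilityReport` list: `mode`, `ari` (per repetition or per
#'   excluded site), `meanARI`, `sdARI`, `reruns` (subsamples redrawn
#'   because a cluster came back empty).
#' @export
stabilityValidation <- function(X, referenceLabels,
                                mode = c("subsample", "loso"),
                                k = length(unique(referenceLabels)),
                                frac = 0.9, reps = 100L, sites = NULL,
                                nInit = 20L, seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(referenceLabels) != n)
    stop("referenceLabels must cover all subjects")
  reruns <- 0L
  if (mode == "subsample") {
    frac <- .assertProb(frac, "frac", 1e-6, 1 - 1e-6)
    reps <- .assertCount(reps, "reps")
    m <- floor(frac * n)
    ari <- numeric(reps)
    set.seed(.childSeed(seed, "subsample"))
    for (r in seq_len(reps)) {
      repeat {
        idx <- sample(n, m)
        km <- kmeansCorrelation(X[idx, , drop = FALSE], k, nInit = nInit,
                                seed = .childSeed(seed, paste0("rep", r,
                                                               reruns)))
        if (all(tabulate(km$labels, k) > 0)) break
        reruns <- reruns + 1L
      }
      ari[r] <- adjustedRandIndex(km$labels, referenceLabels[idx])
    }
    names(ari) <- paste0("rep", seq_len(reps))
  } else {
    if (is.null(sites) || length(unique(sites)) < 2)
      stop("loso mode requires site labels with >= 2 sites")
    us <- unique(sites)
    ari <- setNames(numeric(length(us)), as.character(us))
    for (s in seq_along(us)) {
      idx <- which(sites != us[s])
      km <- kmeansCorrelation(X[idx, , drop = FALSE], k, nInit = nInit,
                              seed = .childSeed(seed, paste0("loso", s)))
      ari[s] <- adjustedRandIndex(km$labels, referenceLabels[idx])
    }
  }
  structure(list(mode = mode, ari = ari, meanARI = mean(ari),
                 sdARI = sd(ari), reruns = reruns),
            class = "StabilityReport")
}
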