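# shared fixtures and independent oracles used across test files

.fixtures <- new.env()

# small multi-site cohort reused by several files (regenerated once)
smallCohort <- function() {
  if (is.null(.fixtures$co))
    .fixtures$co <- generateCohort(cohortConfig(
      nSites = 3, nHCPerSite = 20, nPatPerSite = 16, nRegions = 16,
      seed = 11))
  .fixtures$co
}

# literal pair-counting ARI: walks all subject pairs and counts
# agreements, independent of any contingency-table algebra
pairCountARI <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  np <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / np
  maxidx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxidx == expected) return(0)
  (n11 - expected) / (maxidx - expected)
}

# exhaustive best 2-partition under the correlation-distance objective:
# centroid of a group is its normalized mean direction in row-standardized
# space, objective is the summed correlation distance to the centroid
bruteForce2Means <- function(X) {
  V <- X - rowMeans(X)
  V <- V / sqrt(rowSums(V^2))
  n <- nrow(V)
  best <- list(obj = Inf)
  for (mask in 1:(2^(n - 1) - 1)) {   # fix subject 1 in group 1
    g <- as.integer(intToBits(mask))[seq_len(n)] + 1L
    obj <- 0
    for (j in 1:2) {
      cj <- colSums(V[g == j, , drop = FALSE])
      nrm <- sqrt(sum(cj^2))
      if (nrm == 0) { obj <- Inf; break }
      obj <- obj + sum(1 - (V[g == j, , drop = FALSE] %*% (cj / nrm)))
    }
    if (obj < best$obj) best <- list(obj = obj, labels = g)
  }
  best
}

# naive dominance analysis: refits lm() for every predictor subset
naiveDominance <- function(y, X) {
  k <- ncol(X)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  r2 <- apply(subsets, 1, function(s) {
    if (!any(s)) return(0)
    summary(lm(y ~ X[, s, drop = FALSE]))$r.squared
  })
  key <- apply(subsets, 1, function(s) paste(which(s), collapse = ","))
  r2s <- setNames(r2, key)
  total <- numeric(k)
  for (p in seq_len(k)) {
    cond <- numeric(k)
    for (s in 0:(k - 1)) {
      others <- setdiff(seq_len(k), p)
      combs <- if (s == 0) list(integer(0))
        else if (length(others) == 1) list(others)   # combn scalar trap
        else combn(others, s, simplify = FALSE)
      deltas <- vapply(combs, function(S) {
        with_p <- paste(sort(c(S, p)), collapse = ",")
        without <- paste(sort(S), collapse = ",")
        r2s[[with_p]] - if (without == "") 0 else r2s[[without]]
      }, 0)
      cond[s + 1] <- mean(deltas)
    }
    total[p] <- mean(cond)
  }
  setNames(total, colnames(X))
}
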