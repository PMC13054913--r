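#' Multilinear receptor model of a regional abnormality map
#'
#' OLS of the regional t-map on all receptor density maps plus an
#' intercept. Model significance comes from a permutation null: the region
#' order of the t-map is permuted, the model refitted, and the null R^2
#' collected; `p = (1 + #\{null R^2 >= observed\}) / (nPerm + 1)`.
#' When several subtype models are fitted in one pipeline run, Bonferroni
#' correction across them is applied by the caller ([runPipeline()]).
#'
#' @param tMap `ContrastMap` or numeric per-region abnormality vector.
#' @param atlas a [ReceptorAtlas-class] on the same regions.
#' @param nPerm permutation iterations (default 10000).
#' @param seed integer seed.
#' @return list with `r2`, `adjustedR2`, `coefficients` (named, no
#'   intercept), `fStatistic`, `permutationP`, `nPerm`.
#' @export
receptorModelFit <- function(tMap, atlas, nPerm = 10000L, seed = 1L) {
  y <- if (is.data.frame(tMap)) tMap$t else as.numeric(tMap)
  R <- receptorDensities(atlas)
  if (length(y) != nrow(R)) stop("t-map and atlas region sets differ")
  k <- ncol(R); n <- length(y)
  if (n <= k + 1) stop("need n_regions > n_receptors + 1")
  if (kappa(crossprod(cbind(1, R))) > 1e8) {
    cors <- cor(R)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop("receptor columns nearly collinear (e.g. ",
         colnames(R)[worst[1]], " ~ ", colnames(R)[worst[2]], ")")
  }
  X <- cbind(intercept = 1, R)
  fit <- lm.fit(X, y)
  res <- fit$residuals
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  adjR2 <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  fStat <- (r2 / k) / ((1 - r2) / (n - k - 1))

  nPerm <- .assertCount(nPerm, "nPerm")
  set.seed(.childSeed(seed, "receptorperm"))
  nullR2 <- vapply(seq_len(nPerm), function(i) {
    yp <- y[sample(n)]
    1 - sum(lm.fit(X, yp)$residuals^2) / sum((yp - mean(yp))^2)
  }, 0)
  list(r2 = r2, adjustedR2 = adjR2,
       coefficients = setNames(fit$coefficients[-1], colnames(R)),
       fStatistic = fStat,
       permutationP = .permP(nullR2, r2, side = "ge"),
       nPerm = nPerm)
}

#' Dominance analysis of receptor predictors
#'
#' For every predictor and every sub-model not containing it, the increase
#' in R^2 when the predictor joins is computed; averaging within each
#' sub-model size gives the conditional dominance profile, and averaging
#' the profile gives the total dominance. Totals sum exactly to the
#' full-model R^2. All `2^k` sub-model R^2 values are enumerated (via
#' normal-equation sub-solves of the full cross-product matrix), so `k`
#' is capped.
#'
#' @param tMap `ContrastMap` or numeric per-region abnormality vector.
#' @param atlas a [ReceptorAtlas-class] (or plain predictor matrix).
#' @param maxPredictors refusal threshold for the exponential enumeration.
#' @return a [DominanceResult-class].
#' @export
dominanceAnalysis <- function(tMap, atlas, maxPredictors = 20L) {
  y <- if (is.data.frame(tMap)) tMap$t else as.numeric(tMap)
  R <- if (methods::is(atlas, "ReceptorAtlas")) receptorDensities(atlas)
       else as.matrix(atlas)
  k <- ncol(R); n <- length(y)
  if (k > maxPredictors)
    stop(k, " predictors exceed the dominance cap (", maxPredictors,
         "); screen predictors first", call. = FALSE)
  if (length(y) != nrow(R)) stop("t-map and predictor region sets differ")
  preds <- colnames(R)
  if (is.null(preds)) preds <- sprintf("x%d", seq_len(k))

  # centered cross-products: R^2 of subset S from the normal equations
  yc <- y - mean(y)
  Rc <- sweep(R, 2, colMeans(R))
  Sxx <- crossprod(Rc)
  Sxy <- drop(crossprod(Rc, yc))
  Syy <- sum(yc^2)
  nSub <- 2^k
  r2sub <- numeric(nSub)            # index = bitmask + 1
  for (m in seq_len(nSub - 1)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) > 0)
    beta <- solve(Sxx[S, S, drop = FALSE], Sxy[S])
    r2sub[m + 1] <- sum(beta * Sxy[S]) / Syy
  }
  fullR2 <- r2sub[nSub]
  adjR2 <- 1 - (1 - fullR2) * (n - 1) / (n - k - 1)

  conditional <- matrix(NA_real_, k, k,
                        dimnames = list(preds, paste0("size", 0:(k - 1))))
  for (p in seq_len(k)) {
    pbit <- bitwShiftL(1L, p - 1L)
    delta <- numeric(k); cnt <- integer(k)
    for (m in 0:(nSub - 1)) {
      if (bitwAnd(m, pbit) > 0) next
      s <- .bitCount(m, k)
      delta[s + 1] <- delta[s + 1] + r2sub[m + pbit + 1] - r2sub[m + 1]
      cnt[s + 1] <- cnt[s + 1] + 1L
    }
    conditional[p, ] <- delta / cnt
  }
  total <- rowMeans(conditional)
  methods::new("DominanceResult", fullR2 = fullR2, adjustedR2 = adjR2,
               totalDominance = total,
               relativeDominance = total / fullR2,
               conditional = conditional,
               permutationP = NA_real_, nPermutations = 0L)
}

.bitCount <- function(m, k) {
  s <- 0L
  for (b in 0:(k - 1)) if (bitwAnd(m, bitwShiftL(1L, b)) > 0) s <- s + 1L
  s
}

setMethod("show", "DominanceResult", function(object) {
  cat("DominanceResult: full R^2 =", round(object@fullR2, 4),
      "( adjusted", round(object@adjustedR2, 4), ")\n")
  td <- sort(object@totalDominance, decreasing = TRUE)
  cat("  top predictors:",
      paste(names(head(td, 3)), round(head(td, 3), 4), sep = "=",
            collapse = "  "), "\n")
  invisible(NULL)
})

#' @describeIn dominanceAnalysis named per-predictor total dominance.
#' @param object a `DominanceResult`.
#' @export
totalDominance <- function(object) object@totalDominance

#' Cumulative dominance contributions of excitatory vs inhibitory receptors
#'
#' @param dom a [DominanceResult-class].
#' @param classes named receptor class vector
#'   (`"excitatory"`/`"inhibitory"`), e.g. [receptorClasses()].
#' @return list with `excitatory`, `inhibitory` (summed total dominance),
#'   and `excitatoryShare`, `inhibitoryShare` (fractions of full R^2).
#' @export
classContribution <- function(dom, classes) {
  td <- totalDominance(dom)
  if (!all(names(td) %in% names(classes)))
    stop("unclassified receptor(s): ",
         paste(setdiff(names(td), names(classes)), collapse = ", "))
  cls <- classes[names(td)]
  exc <- sum(td[cls == "excitatory"])
  inh <- sum(td[cls == "inhibitory"])
  list(excitatory = exc, inhibitory = inh,
       excitatoryShare = exc / dom@fullR2,
       inhibitoryShare = inh / dom@fullR2)
}
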