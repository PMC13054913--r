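#' Disease-epicenter identification by rank and permutation
#'
#' A region is epicenter-like when both its own abnormality and its
#' transcriptomic neighbors' abnormality are extreme. Regions are ranked
#' by the abnormality map `d` and by the neighbor deviation `dTilde`
#' (ascending: most negative first, appropriate for decrease-dominated
#' maps; descending for increase-dominated maps); the mean of the two
#' ranks is the epicenter likelihood. The null permutes `d` over regions,
#' recomputing `dTilde` and the mean rank each time;
#' `p_i = (1 + #\{null meanRank_i <= observed_i\}) / (nPerm + 1)`
#' (one-sided: at least as epicenter-like as chance). Regions with no
#' positive connections are excluded.
#'
#' @param cge CGE connectome ([buildCGE()]).
#' @param d per-region abnormality map (vector or `ContrastMap`).
#' @param direction `"ascending"` or `"descending"`.
#' @param nPerm permutations (a warning is issued below 1000: the p
#'   resolution would not support alpha = 0.01).
#' @param alpha epicenter significance level (default 0.01).
#' @param seed integer seed.
#' @return an [EpicenterResult-class].
#' @export
epicenterTest <- function(cge, d, direction = c("ascending", "descending"),
                          nPerm = 10000L, alpha = 0.01, seed = 1L) {
  direction <- match.arg(direction)
  if (is.data.frame(d)) d <- setNames(d$t, d$region)
  d <- as.numeric(d)
  if (length(d) != nrow(cge)) stop("dimension mismatch", call. = FALSE)
  nPerm <- .assertCount(nPerm, "nPerm")
  if (nPerm < 1000)
    warning("nPerm < 1000: p resolution insufficient for alpha = 0.01")
  regions <- rownames(cge)
  if (is.null(regions)) regions <- sprintf("R%03d", seq_len(nrow(cge)))

  Ni <- rowSums(cge > 0)
  use <- Ni > 0
  W <- cge[use, use, drop = FALSE]
  NiU <- rowSums(W > 0)
  sgn <- if (direction == "ascending") 1 else -1
  dU <- d[use]
  nU <- sum(use)

  meanRankOf <- function(dv) {
    dt <- drop(W %*% dv)
    dt[NiU > 0] <- dt[NiU > 0] / NiU[NiU > 0]
    (rank(sgn * dv, ties.method = "average") +
       rank(sgn * dt, ties.method = "average")) / 2
  }
  obs <- meanRankOf(dU)
  dtObs <- drop(W %*% dU); dtObs[NiU > 0] <- dtObs[NiU > 0] / NiU[NiU > 0]

  set.seed(.childSeed(seed, "epicenter"))
  hits <- numeric(nU)
  for (b in seq_len(nPerm)) {
    nullRank <- meanRankOf(dU[sample(nU)])
    hits <- hits + (nullRank <= obs)
  }
  p <- (1 + hits) / (nPerm + 1)

  tab <- data.frame(region = regions[use], d = dU, dTilde = dtObs,
                    ownRank = rank(sgn * dU, ties.method = "average"),
                    neighborRank = rank(sgn * dtObs,
                                        ties.method = "average"),
                    meanRank = obs, p = p, isEpicenter = p < alpha,
                    row.names = NULL)
  methods::new("EpicenterResult", table = tab, direction = direction,
               alpha = alpha, nPerm = as.integer(nPerm),
               undefinedRegions = regions[!use])
}

setMethod("show", "EpicenterResult", function(object) {
  tab <- object@table
  cat("EpicenterResult:", sum(tab$isEpicenter), "epicenter(s) of",
      nrow(tab), "regions ( direction:", object@direction,
      ", alpha =", object@alpha, ",", object@nPerm, "permutations )\n")
  if (sum(tab$isEpicenter))
    cat("  epicenters:",
        paste(head(tab$region[tab$isEpicenter], 8), collapse = ", "),
        "\n")
  if (length(object@undefinedRegions))
    cat("  excluded (no connections):",
        length(object@undefinedRegions), "region(s)\n")
  invisible(NULL)
})

#' @describeIn epicenterTest ranking table as a data.frame.
#' @param object an `EpicenterResult`.
#' @export
epicenterTable <- function(object) object@table

#' @describeIn epicenterTest region ids designated as epicenters.
#' @export
epicenterRegions <- function(object)
  object@table$region[object@table$isEpicenter]

#' Read / write a CGE connectome as square TSV
#'
#' @param cge region x region matrix.
#' @param path file path.
#' @export
writeCGE <- function(cge, path) {
  df <- data.frame(region = rownames(cge), cge, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCGE
#' @export
readCGE <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  m
}
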