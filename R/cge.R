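#' Build the correlated gene expression (CGE) connectome
#'
#' Each gene is Z-scored across regions; the connectome entry `w_ij` is
#' the Pearson correlation between the expression profiles of regions i
#' and j. Negative correlations are set to zero (only positive
#' transcriptomic similarity is retained) and the diagonal is zeroed.
#'
#' @param expr regions x genes expression matrix (>= 3 genes, no constant
#'   region rows).
#' @return symmetric nonnegative regions x regions matrix with zero
#'   diagonal.
#' @export
buildCGE <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need >= 3 genes", call. = FALSE)
  sds <- apply(expr, 1, sd)
  if (any(sds == 0))
    stop("constant expression row(s): ",
         paste(head(rownames(expr)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  Z <- apply(expr, 2, function(g) if (sd(g) == 0) g * 0 else .zscore(g))
  W <- cor(t(Z))
  W[W < 0] <- 0
  diag(W) <- 0
  W <- (W + t(W)) / 2
  stopifnot(all(W >= 0), max(abs(W - t(W))) < 1e-12)
  W
}

#' Neighbor deviation: CGE-weighted mean abnormality of neighbors
#'
#' For region i with `N_i` positively connected neighbors,
#' `dTilde_i = (1 / N_i) * sum_\{j: w_ij > 0\} w_ij * d_j`: the collective
#' abnormality of region i's transcriptomic neighborhood, normalized by
#' neighbor count. Regions without positive connections are undefined and
#' excluded downstream.
#'
#' @param cge symmetric nonnegative region x region matrix
#'   ([buildCGE()]).
#' @param d per-region abnormality vector (unthresholded t-map).
#' @return list with `dTilde` (named vector, NA where undefined),
#'   `neighborCount`, `undefinedRegions`.
#' @export
neighborDeviation <- function(cge, d) {
  if (is.data.frame(d)) d <- setNames(d$t, d$region)
  d <- as.numeric(d)
  if (length(d) != nrow(cge)) stop("dimension mismatch", call. = FALSE)
  Ni <- rowSums(cge > 0)
  dTilde <- drop(cge %*% d)
  dTilde[Ni > 0] <- dTilde[Ni > 0] / Ni[Ni > 0]
  dTilde[Ni == 0] <- NA_real_
  regions <- rownames(cge)
  if (is.null(regions)) regions <- sprintf("R%03d", seq_len(nrow(cge)))
  list(dTilde = setNames(dTilde, regions),
       neighborCount = setNames(Ni, regions),
       undefinedRegions = regions[Ni == 0])
}

#' Compare deviation-connectome coupling between a subtype and all patients
#'
#' Coupling is the Pearson correlation between a map and its neighbor
#' deviation, `cor(d, dTilde)`. The subtype's coupling and the
#' all-patients coupling are dependent, non-overlapping correlations on
#' the same regions; they are compared with Steiger's Z computed from
#' Fisher-transformed r's and the asymptotic covariance built from all
#' six pairwise correlations among `d_subtype, dTilde_subtype, d_all,
#' dTilde_all`. Regions with undefined neighbor deviation are excluded
#' listwise.
#'
#' @param dSubtype,dAll per-region abnormality maps (vectors or
#'   `ContrastMap`s) on the regions of `cge`.
#' @param cge the CGE connectome.
#' @return list with `rSubtype`, `rAll`, `steigerZ`, `p` (two-sided),
#'   `n` (regions used).
#' @export
couplingAndCompare <- function(dSubtype, dAll, cge) {
  d1 <- if (is.data.frame(dSubtype)) dSubtype$t else as.numeric(dSubtype)
  d2 <- if (is.data.frame(dAll)) dAll$t else as.numeric(dAll)
  nd1 <- neighborDeviation(cge, d1)$dTilde
  nd2 <- neighborDeviation(cge, d2)$dTilde
  keep <- !is.na(nd1) & !is.na(nd2)
  n <- sum(keep)
  if (n < 10) stop("fewer than 10 usable regions", call. = FALSE)
  M <- cbind(d1[keep], nd1[keep], d2[keep], nd2[keep])
  C <- cor(M)
  st <- steigerZ(C[1, 2], C[3, 4], C[1, 3], C[1, 4], C[2, 3], C[2, 4], n)
  list(rSubtype = C[1, 2], rAll = C[3, 4], steigerZ = st$z, p = st$p,
       n = n)
}

#' Steiger's Z for two dependent, non-overlapping correlations
#'
#' Compares `r12` and `r34` measured on the same n cases, accounting for
#' the dependence through the remaining four correlations. Fisher
#' transforms are differenced and scaled by the asymptotic covariance
#' evaluated at the pooled correlation (Steiger's Z2* statistic).
#'
#' @param r12,r34 the two correlations under comparison.
#' @param r13,r14,r23,r24 the cross-correlations among the four variables.
#' @param n number of cases.
#' @return list with `z` and two-sided `p`.
#' @export
steigerZ <- function(r12, r34, r13, r14, r23, r24, n) {
  if (n < 10) stop("n too small for the asymptotic test", call. = FALSE)
  z1 <- atanh(r12); z2 <- atanh(r34)
  rbar <- (r12 + r34) / 2
  # covariance of r12 and r34 (Pearson-Filon), evaluated at pooled rbar
  psi <- 0.5 * ((r13 - rbar * r23) * (r24 - r23 * rbar) +
                (r14 - r13 * rbar) * (r23 - r13 * rbar) +
                (r13 - r14 * rbar) * (r24 - r14 * rbar) +
                (r14 - rbar * r24) * (r23 - r24 * rbar))
  s <- psi / (1 - rbar^2)^2
  z <- sqrt(n - 3) * (z1 - z2) / sqrt(2 - 2 * s)
  list(z = z, p = 2 * pnorm(-abs(z)))
}
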