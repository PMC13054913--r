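#' Construct a receptor atlas
#'
#' @param densities regions x receptors density matrix (named columns).
#' @param receptorClass character vector (`"excitatory"`/`"inhibitory"`),
#'   one per receptor, named or in column order.
#' @param system optional neurotransmitter-system labels.
#' @param zScore Z-score each column across regions (the standard input
#'   convention); set `FALSE` only if the input is already Z-scored.
#' @return a [ReceptorAtlas-class].
#' @export
ReceptorAtlas <- function(densities, receptorClass,
                          system = rep("unknown", ncol(densities)),
                          zScore = TRUE) {
  densities <- as.matrix(densities)
  if (is.null(colnames(densities)))
    colnames(densities) <- sprintf("receptor%02d", seq_len(ncol(densities)))
  if (zScore) densities <- apply(densities, 2, .zscore)
  if (is.null(names(receptorClass))) names(receptorClass) <- colnames(densities)
  if (is.null(names(system))) names(system) <- colnames(densities)
  methods::new("ReceptorAtlas", densities = densities,
               receptorClass = receptorClass[colnames(densities)],
               system = system[colnames(densities)])
}

#' @describeIn ReceptorAtlas Z-scored regions x receptors density matrix.
#' @param x a `ReceptorAtlas`.
#' @export
receptorDensities <- function(x) x@densities

#' @describeIn ReceptorAtlas named excitatory/inhibitory class vector.
#' @export
receptorClasses <- function(x) x@receptorClass

setMethod("show", "ReceptorAtlas", function(object) {
  cat("ReceptorAtlas:", nrow(object@densities), "regions x",
      ncol(object@densities), "receptors (",
      sum(object@receptorClass == "excitatory"), "excitatory /",
      sum(object@receptorClass == "inhibitory"), "inhibitory )\n")
  invisible(NULL)
})

#' Generate synthetic molecular assets (expression + receptor maps)
#'
#' Builds a regions x genes expression matrix with community-block means
#' (so the derived correlated-gene-expression connectome is modular) and a
#' set of receptor density maps, each a known mixture of the subtype
#' deviation pattern and an independent smooth nuisance field plus noise.
#' A receptor->weight coefficient vector (nonzero on excitatory receptors
#' by default) is recorded so that abnormality maps with known molecular
#' composition can be synthesized via [receptorMixtureMap()].
#'
#' @param truth ground-truth list from [generateCohort()] (supplies region
#'   ids and the subtype pattern).
#' @param nGenes number of genes (>= 10).
#' @param nReceptors number of receptor maps (>= 2; a warning is issued
#'   above the 20-predictor dominance-analysis cap).
#' @param mapNoiseSd SD of i.i.d. noise added to each receptor map.
#' @param nCommunities number of expression communities (>= 2).
#' @param withinGeneNoiseSd SD of gene-level expression noise around the
#'   community means.
#' @param patternLoadings optional per-receptor loading on the subtype
#'   pattern (default: drawn from `[0.2, 0.5]` with random sign).
#' @param nuisanceSd scale of each receptor's smooth nuisance field (0
#'   removes it).
#' @param patternSupport `"class"` (default): excitatory receptors load on
#'   the cerebral-like block of the pattern and inhibitory receptors on
#'   the cerebellar-like block, so the two classes are not confounded and
#'   class-level attribution is identifiable; `"full"`: every receptor
#'   loads on the full signed pattern.
#' @param seed integer seed.
#' @return list with `expression` (regions x genes matrix, with a
#'   `community` attribute), `atlas` (a [ReceptorAtlas-class]), and `truth`
#'   (input truth extended with `receptorCoefficients`, `patternLoadings`,
#'   `communityAssignment`).
#' @export
generateMolecularAssets <- function(truth, nGenes = 200L, nReceptors = 8L,
                                    mapNoiseSd = 0.1, nCommunities = 2L,
                                    withinGeneNoiseSd = 0.5,
                                    patternLoadings = NULL, nuisanceSd = 1,
                                    patternSupport = c("class", "full"),
                                    seed = 1L) {
  patternSupport <- match.arg(patternSupport)
  nGenes <- .assertCount(nGenes, "nGenes", min = 10L)
  nReceptors <- .assertCount(nReceptors, "nReceptors", min = 1L)
  nCommunities <- .assertCount(nCommunities, "nCommunities", min = 2L)
  if (nReceptors > 20L)
    warning("more than 20 receptors exceeds the dominance-analysis cap; ",
            "downstream dominance analysis will refuse the full set")
  regions <- truth$regions
  G <- length(regions)
  set.seed(.childSeed(seed, "molecular"))

  community <- rep(seq_len(nCommunities), length.out = G)
  community <- sort(community)
  mu <- matrix(rnorm(nCommunities * nGenes, 0, 1), nCommunities, nGenes)
  expr <- mu[community, , drop = FALSE] +
    matrix(rnorm(G * nGenes, 0, withinGeneNoiseSd), G, nGenes)
  dimnames(expr) <- list(regions, sprintf("gene%04d", seq_len(nGenes)))
  attr(expr, "community") <- setNames(community, regions)

  pattern <- as.numeric(truth$pattern1)
  # moderate loading: receptor maps associate with the disease pattern
  # without becoming near-collinear with one another
  if (is.null(patternLoadings)) {
    patternLoadings <- runif(nReceptors, 0.2, 0.5) *
      sample(c(-1, 1), nReceptors, replace = TRUE)
  } else patternLoadings <- rep_len(patternLoadings, nReceptors)
  cls <- rep(c("excitatory", "inhibitory"), length.out = nReceptors)
  # class-specific pattern supports keep the two receptor classes
  # unconfounded: excitatory maps track the cerebral-like block,
  # inhibitory maps the cerebellar-like block
  inA <- regions %in% truth$blockA
  inB <- regions %in% truth$blockB
  idx <- seq_len(G) / G
  maps <- matrix(0, G, nReceptors)
  for (k in seq_len(nReceptors)) {
    base <- if (patternSupport == "full") pattern
            else if (cls[k] == "excitatory") pattern * inA
            else pattern * inB
    # smooth nuisance field at a receptor-specific harmonic frequency:
    # sinusoids at distinct integer frequencies are orthogonal on the
    # region grid, so receptor maps do not collide through their
    # nuisance structure and per-receptor attribution stays identifiable
    nuis <- sin(2 * pi * k * idx + runif(1, 0, 2 * pi))
    if (nuisanceSd > 0 && sd(nuis) > 0) nuis <- nuis / sd(nuis)
    maps[, k] <- patternLoadings[k] * base +
      nuisanceSd * nuis + rnorm(G, 0, mapNoiseSd)
  }
  rownames(maps) <- regions
  colnames(maps) <- sprintf("receptor%02d", seq_len(nReceptors))
  atlas <- ReceptorAtlas(maps, cls)

  w <- numeric(nReceptors)
  exc <- which(cls == "excitatory")
  w[exc] <- runif(length(exc), 0.8, 1.5) *
    sample(c(-1, 1), length(exc), replace = TRUE)
  names(w) <- colnames(maps)

  truth$receptorCoefficients <- w
  truth$patternLoadings <- setNames(patternLoadings, colnames(maps))
  truth$communityAssignment <- attr(expr, "community")
  list(expression = expr, atlas = atlas, truth = truth)
}

#' Synthesize an abnormality map as a known receptor mixture
#'
#' @param atlas a [ReceptorAtlas-class].
#' @param coefficients named receptor->weight vector (e.g.
#'   `truth$receptorCoefficients`).
#' @param noiseSd SD of added i.i.d. noise.
#' @param seed integer seed for the noise.
#' @return named per-region numeric vector `densities %*% coefficients +
#'   noise`.
#' @export
receptorMixtureMap <- function(atlas, coefficients, noiseSd = 0, seed = 1L) {
  R <- receptorDensities(atlas)
  stopifnot(all(names(coefficients) %in% colnames(R)))
  w <- setNames(numeric(ncol(R)), colnames(R))
  w[names(coefficients)] <- coefficients
  set.seed(.childSeed(seed, "mixture"))
  drop(R %*% w) + rnorm(nrow(R), 0, noiseSd)
}

#' Diffuse a planted epicenter pattern along the CGE connectome
#'
#' Starting from `amplitude` on the epicenter regions and 0 elsewhere, the
#' deviation field is iterated as
#' `d[t+1] = (1 - beta) * d[t] + beta * Wbar %*% d[t]`,
#' where `Wbar` is the row-normalized positive CGE matrix. Regions with no
#' positive connections are excluded from normalization and keep their
#' value (with a warning).
#'
#' @param cge symmetric nonnegative region x region matrix (see
#'   [buildCGE()]).
#' @param epicenters region names or indices seeded with the deviation.
#' @param amplitude initial deviation at the epicenters (sign carries the
#'   direction of abnormality).
#' @param beta diffusion weight in `[0, 1)`.
#' @param nSteps number of diffusion steps (>= 0).
#' @return named per-region deviation vector.
#' @export
injectEpicenterPattern <- function(cge, epicenters, amplitude = -1,
                                   beta = 0.5, nSteps = 10L) {
  stopifnot(is.matrix(cge), nrow(cge) == ncol(cge))
  if (length(epicenters) == 0) stop("epicenters must be nonempty")
  if (beta < 0 || beta >= 1) stop("beta must lie in [0, 1)")
  nSteps <- .assertCount(nSteps, "nSteps", min = 0L)
  G <- nrow(cge)
  regions <- rownames(cge)
  if (is.null(regions)) regions <- sprintf("R%03d", seq_len(G))
  d <- setNames(numeric(G), regions)
  if (is.character(epicenters)) epicenters <- match(epicenters, regions)
  if (anyNA(epicenters) || any(epicenters < 1 | epicenters > G))
    stop("epicenters must index regions of the CGE matrix")
  d[epicenters] <- amplitude
  rs <- rowSums(cge)
  isolated <- rs == 0
  if (any(isolated))
    warning(sum(isolated), " region(s) with no positive connections ",
            "propagate unchanged")
  Wbar <- cge
  Wbar[!isolated, ] <- cge[!isolated, , drop = FALSE] / rs[!isolated]
  for (t in seq_len(nSteps)) {
    avg <- drop(Wbar %*% d)
    avg[isolated] <- d[isolated]
    d <- (1 - beta) * d + beta * avg
  }
  d
}
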