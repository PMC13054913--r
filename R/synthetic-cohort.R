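#' Configuration of a synthetic multi-site cohort
#'
#' Defines the generative model for a multi-site structural-imaging cohort:
#' per-region baselines with age and sex effects, ComBat-style additive and
#' multiplicative site effects, and two patient subtypes carrying opposite
#' deviation patterns on disjoint region blocks (a "cerebral-like" block
#' where subtype 1 gains volume and a "cerebellar-like" block where it loses
#' volume; subtype 2 is the mirror image).
#'
#' @param nSites number of acquisition sites (>= 2 for leave-one-site-out).
#' @param nHCPerSite,nPatPerSite healthy controls / patients per site.
#' @param nRegions number of atlas regions (default 60; supports up to 268).
#' @param ageRange length-2 numeric, uniform age range in years.
#' @param sexBalance proportion female (sex coded 1).
#' @param betaAge per-region GMV change per year; a single value is
#'   recycled, `NULL` draws region-specific slopes in `[-0.02, -0.005]`.
#' @param betaSex per-region GMV offset for sex = 1; `NULL` draws from
#'   `[-0.2, 0.2]`.
#' @param siteShiftSd SD of the per-site, per-region additive shift
#'   (GMV units).
#' @param siteScaleRange length-2 interval for the per-site, per-region
#'   multiplicative scale on the residual.
#' @param subtypeEffect subtype pattern amplitude in residual-SD units.
#' @param patternFraction fraction of regions in each subtype block
#'   (0 < f <= 0.5; the two blocks are disjoint).
#' @param noiseSd residual SD in GMV units.
#' @param seed integer seed; all generation is deterministic given the
#'   config.
#' @return a `CohortConfig` (validated list).
#' @export
cohortConfig <- function(nSites = 4L, nHCPerSite = 50L, nPatPerSite = 50L,
                         nRegions = 60L, ageRange = c(18, 65),
                         sexBalance = 0.55, betaAge = NULL, betaSex = NULL,
                         siteShiftSd = 0.4, siteScaleRange = c(0.8, 1.25),
                         subtypeEffect = 1.5, patternFraction = 0.2,
                         noiseSd = 0.5, seed = 1L) {
  cfg <- list(
    nSites = .assertCount(nSites, "nSites"),
    nHCPerSite = .assertCount(nHCPerSite, "nHCPerSite"),
    nPatPerSite = .assertCount(nPatPerSite, "nPatPerSite"),
    nRegions = .assertCount(nRegions, "nRegions", min = 4L),
    ageRange = sort(as.numeric(ageRange)),
    sexBalance = .assertProb(sexBalance, "sexBalance"),
    betaAge = betaAge, betaSex = betaSex,
    siteShiftSd = .assertProb(siteShiftSd, "siteShiftSd", 0, Inf),
    siteScaleRange = sort(as.numeric(siteScaleRange)),
    subtypeEffect = as.numeric(subtypeEffect),
    patternFraction = .assertProb(patternFraction, "patternFraction",
                                  0, 0.5),
    noiseSd = .assertProb(noiseSd, "noiseSd", 0, Inf),
    seed = .assertCount(seed, "seed", min = 0L))
  if (cfg$patternFraction * cfg$nRegions < 1)
    stop("patternFraction * nRegions must be >= 1", call. = FALSE)
  if (cfg$siteScaleRange[1] <= 0)
    stop("site scale factors must be positive", call. = FALSE)
  class(cfg) <- "CohortConfig"
  cfg
}

#' Generate a synthetic multi-site cohort with known ground truth
#'
#' Regional GMV for subject i at region g is
#' `baseline_g + betaAge_g * age_i + betaSex_g * sex_i + shift_{s(i),g} +
#'  scale_{s(i),g} * (eps_ig + pattern_g * subtypeEffect * noiseSd)`,
#' with `eps ~ N(0, noiseSd^2)`; the pattern term is present only in
#' patients (subtype 1 carries `pattern1`, subtype 2 carries
#' `-pattern1`). Patients are split evenly between subtypes within site.
#'
#' @param config a [cohortConfig()].
#' @return a [GMVExperiment-class] whose `colData` includes
#'   `subtype_truth` (`"HC"`, `"subtype1"`, `"subtype2"`) and whose
#'   metadata carries the `groundTruth` list (site parameters, covariate
#'   slopes, signed pattern vectors, block indices).
#' @examples
#' cohort <- generateCohort(cohortConfig(nSites = 2, nHCPerSite = 15,
#'                                       nPatPerSite = 15, nRegions = 20,
#'                                       seed = 7))
#' table(participants(cohort)$subtype_truth)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  G <- config$nRegions
  regions <- sprintf("R%03d", seq_len(G))

  baseline <- runif(G, 3, 9)
  betaAge <- if (is.null(config$betaAge)) runif(G, -0.02, -0.005)
             else rep_len(config$betaAge, G)
  betaSex <- if (is.null(config$betaSex)) runif(G, -0.2, 0.2)
             else rep_len(config$betaSex, G)

  m <- max(1L, round(config$patternFraction * G))
  if (2L * m > G) stop("pattern blocks exceed the region count")
  blockA <- seq_len(m)            # "cerebral-like": subtype 1 increases
  blockB <- m + seq_len(m)        # "cerebellar-like": subtype 1 decreases
  pattern1 <- numeric(G)
  pattern1[blockA] <- 1
  pattern1[blockB] <- -1
  pattern2 <- -pattern1

  shift <- matrix(rnorm(config$nSites * G, 0, config$siteShiftSd),
                  config$nSites, G)
  scale <- matrix(runif(config$nSites * G, config$siteScaleRange[1],
                        config$siteScaleRange[2]), config$nSites, G)

  nPerSite <- config$nHCPerSite + config$nPatPerSite
  n <- config$nSites * nPerSite
  site <- rep(sprintf("site%02d", seq_len(config$nSites)), each = nPerSite)
  siteIdx <- rep(seq_len(config$nSites), each = nPerSite)
  group <- rep(rep(c("HC", "MDD"), c(config$nHCPerSite,
                                     config$nPatPerSite)), config$nSites)
  # balanced subtype assignment within site, order randomized
  subtype <- rep("HC", n)
  for (s in seq_len(config$nSites)) {
    pat <- which(siteIdx == s & group == "MDD")
    half <- ceiling(length(pat) / 2)
    lab <- sample(rep(c("subtype1", "subtype2"),
                      c(half, length(pat) - half)))
    subtype[pat] <- lab
  }
  age <- runif(n, config$ageRange[1], config$ageRange[2])
  sex <- rbinom(n, 1, config$sexBalance)

  eps <- matrix(rnorm(n * G, 0, config$noiseSd), n, G)
  patEffect <- matrix(0, n, G)
  amp <- config$subtypeEffect * config$noiseSd
  n1 <- sum(subtype == "subtype1"); n2 <- sum(subtype == "subtype2")
  if (n1 > 0)
    patEffect[subtype == "subtype1", ] <-
      matrix(pattern1 * amp, n1, G, byrow = TRUE)
  if (n2 > 0)
    patEffect[subtype == "subtype2", ] <-
      matrix(pattern2 * amp, n2, G, byrow = TRUE)

  gmv <- matrix(baseline, n, G, byrow = TRUE) +
    outer(age, betaAge) + outer(sex, betaSex) +
    shift[siteIdx, ] + scale[siteIdx, ] * (eps + patEffect)
  colnames(gmv) <- regions

  pt <- data.frame(
    participant_id = sprintf("sub%04d", seq_len(n)),
    age = age, sex = sex, site = site, group = group,
    subtype_truth = subtype, stringsAsFactors = FALSE)
  rownames(gmv) <- pt$participant_id

  truth <- list(
    regions = regions, baseline = baseline,
    betaAge = betaAge, betaSex = betaSex,
    siteShift = shift, siteScale = scale,
    pattern1 = setNames(pattern1, regions),
    pattern2 = setNames(pattern2, regions),
    blockA = regions[blockA], blockB = regions[blockB],
    subtypeEffect = config$subtypeEffect,
    noiseSd = config$noiseSd, config = config)
  GMVExperiment(gmv, pt, metadata = list(groundTruth = truth))
}
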