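#' Configuration for an end-to-end pipeline run
#'
#' All randomness flows from `seed` (per-stage seeds are derived from it
#' and recorded in the bundle). Stage toggles allow partial runs; an
#' enabled stage whose inputs are missing fails the pre-flight check
#' before any computation.
#'
#' @param cohort a [cohortConfig()] (synthetic mode) or a list with
#'   `matrixPath` and `participantsPath` (real-data mode).
#' @param expression optional regions x genes matrix, or a path to its
#'   TSV (region-id first column); synthetic mode can generate it.
#' @param receptors optional [ReceptorAtlas-class]; synthetic mode can
#'   generate one.
#' @param stages character subset of
#'   `c("harmonize","normative","crossval","subtype","contrasts",
#'      "molecular","epicenter")`.
#' @param kRange candidate cluster numbers.
#' @param extremeThreshold deviation cutoff for overlap maps.
#' @param alphaContrast family alpha for regional contrasts.
#' @param alphaEpicenter epicenter permutation alpha.
#' @param nPermMolecular,nPermEpicenter permutation counts.
#' @param cvRepeats k-fold repetitions for the validation stage.
#' @param nInit K-means restarts.
#' @param stabilityReps subsample-stability repetitions.
#' @param outDir output directory (`NULL`: nothing written).
#' @param seed master seed.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(cohort = cohortConfig(),
                           expression = NULL, receptors = NULL,
                           stages = c("harmonize", "normative", "crossval",
                                      "subtype", "contrasts", "molecular",
                                      "epicenter"),
                           kRange = 2:10, extremeThreshold = 1.96,
                           alphaContrast = 0.05, alphaEpicenter = 0.01,
                           nPermMolecular = 10000L, nPermEpicenter = 10000L,
                           cvRepeats = 2L, nInit = 100L,
                           stabilityReps = 100L, outDir = NULL,
                           seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(cohort = cohort, expression = expression,
              receptors = receptors, stages = stages, kRange = kRange,
              extremeThreshold = extremeThreshold,
              alphaContrast = alphaContrast,
              alphaEpicenter = alphaEpicenter,
              nPermMolecular = .assertCount(nPermMolecular,
                                            "nPermMolecular"),
              nPermEpicenter = .assertCount(nPermEpicenter,
                                            "nPermEpicenter"),
              cvRepeats = .assertCount(cvRepeats, "cvRepeats"),
              nInit = .assertCount(nInit, "nInit"),
              stabilityReps = .assertCount(stabilityReps, "stabilityReps"),
              outDir = outDir, seed = .assertCount(seed, "seed", 0L))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full subtype-discovery pipeline
#'
#' Stage order: harmonize -> normative fit (+ optional cross-validation)
#' -> patient deviation Z-scores and extreme-deviation overlap maps ->
#' SigClust + ensemble subtyping + stability -> regional contrasts ->
#' receptor models with dominance analysis -> CGE coupling and epicenter
#' mapping. Identical config and seed give an identical bundle.
#'
#' @param config a [pipelineConfig()].
#' @return a `ReportBundle` list with per-stage results and a
#'   machine-readable `summary`; written to `config$outDir` when set.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  st <- config$stages
  seed <- config$seed
  bundle <- list(config = config, completed = character(0))

  # ---- inputs (pre-flight) ----
  synthetic <- inherits(config$cohort, "CohortConfig")
  if (synthetic) {
    cohort <- generateCohort(config$cohort)
  } else {
    if (is.null(config$cohort$matrixPath) ||
        is.null(config$cohort$participantsPath))
      stop("real-data mode needs matrixPath and participantsPath")
    cohort <- readGMVExperiment(config$cohort$matrixPath,
                                config$cohort$participantsPath)
  }
  needMolecular <- any(c("molecular", "epicenter") %in% st)
  expr <- config$expression
  atlas <- config$receptors
  if (needMolecular && synthetic &&
      (is.null(expr) || is.null(atlas))) {
    assets <- generateMolecularAssets(groundTruth(cohort),
                                      seed = .childSeed(seed, "assets"))
    if (is.null(expr)) expr <- assets$expression
    if (is.null(atlas)) atlas <- assets$atlas
    bundle$molecularTruth <- assets$truth
  }
  if (is.character(expr)) {
    df <- read.delim(expr, sep = "\t", check.names = FALSE)
    expr <- as.matrix(df[, -1, drop = FALSE]); rownames(expr) <- df[[1]]
  }
  if ("molecular" %in% st && is.null(atlas))
    stop("molecular stage enabled but no receptor atlas available")
  if ("epicenter" %in% st && is.null(expr))
    stop("epicenter stage enabled but no expression matrix available")
  bundle$cohort <- cohort

  # ---- harmonize ----
  if ("harmonize" %in% st) {
    harm <- combatHarmonize(cohort)
    cohort <- harm$experiment
    bundle$combatModel <- harm$model
    bundle$completed <- c(bundle$completed, "harmonize")
  }

  # ---- normative ----
  models <- fitNormative(cohort, seed = .childSeed(seed, "normative"))
  bundle$normativeModels <- models
  if ("crossval" %in% st) {
    bundle$cvKfold <- crossvalidateNormative(
      cohort, scheme = "kfold", nRepeats = config$cvRepeats,
      seed = .childSeed(seed, "cvk"))
    bundle$cvLoso <- crossvalidateNormative(
      cohort, scheme = "loso", seed = .childSeed(seed, "cvl"))
    bundle$completed <- c(bundle$completed, "crossval")
  }
  Z <- deviationZScores(models, cohort)
  bundle$deviations <- Z
  bundle$overlapMaps <- extremeDeviationMaps(Z, config$extremeThreshold)
  bundle$completed <- c(bundle$completed, "normative")

  # ---- subtype ----
  if ("subtype" %in% st) {
    bundle$sigclust <- sigClust(Z, nSim = 1000L,
                                seed = .childSeed(seed, "sigclust"))
    sub <- selectKEnsemble(Z, kRange = config$kRange,
                           nInit = config$nInit,
                           seed = .childSeed(seed, "selectk"))
    bundle$subtypes <- sub
    pt <- participants(cohort)
    patSites <- pt$site[pt$group != "HC"]
    bundle$stabilitySubsample <- stabilityValidation(
      Z, subtypeLabels(sub), mode = "subsample", k = kSelected(sub),
      reps = config$stabilityReps, nInit = 20L,
      seed = .childSeed(seed, "stabsub"))
    bundle$stabilityLoso <- stabilityValidation(
      Z, subtypeLabels(sub), mode = "loso", k = kSelected(sub),
      sites = patSites, nInit = 20L,
      seed = .childSeed(seed, "stabloso"))
    bundle$completed <- c(bundle$completed, "subtype")
  }

  # ---- contrasts ----
  if ("contrasts" %in% st) {
    if (is.null(bundle$subtypes))
      stop("contrasts stage requires the subtype stage")
    pt <- participants(cohort)
    isHC <- pt$group == "HC"
    lab <- rep(NA_integer_, nrow(pt))
    lab[!isHC] <- subtypeLabels(bundle$subtypes)
    maps <- list()
    for (kk in sort(unique(lab[!isHC]))) {
      subset <- isHC | (!is.na(lab) & lab == kk)
      maps[[paste0("subtype", kk)]] <-
        glmGroupContrast(cohort, group = !isHC,
                         alpha = config$alphaContrast, subset = subset)
    }
    maps$allPatients <- glmGroupContrast(cohort, group = !isHC,
                                         alpha = config$alphaContrast)
    bundle$contrastMaps <- maps
    if (length(maps) >= 3)
      bundle$subtypeMapCorrelation <-
        spatialCorrelation(maps[[1]], maps[[2]])
    bundle$demographics <- compareDemographics(pt[!isHC, , drop = FALSE],
                                               lab[!isHC])
    bundle$completed <- c(bundle$completed, "contrasts")
  }

  # ---- molecular ----
  if ("molecular" %in% st) {
    if (is.null(bundle$contrastMaps))
      stop("molecular stage requires the contrasts stage")
    subMaps <- bundle$contrastMaps[
      grep("^subtype", names(bundle$contrastMaps))]
    nModels <- length(subMaps)
    mol <- list()
    for (nm in names(subMaps)) {
      fit <- receptorModelFit(subMaps[[nm]], atlas,
                              nPerm = config$nPermMolecular,
                              seed = .childSeed(seed, paste0("rm", nm)))
      fit$pBonferroni <- min(1, fit$permutationP * nModels)
      dom <- dominanceAnalysis(subMaps[[nm]], atlas)
      mol[[nm]] <- list(fit = fit, dominance = dom,
                        classes = classContribution(
                          dom, receptorClasses(atlas)))
    }
    bundle$molecular <- mol
    bundle$completed <- c(bundle$completed, "molecular")
  }

  # ---- epicenter ----
  if ("epicenter" %in% st) {
    if (is.null(bundle$contrastMaps))
      stop("epicenter stage requires the contrasts stage")
    cge <- buildCGE(expr)
    bundle$cge <- cge
    subMaps <- bundle$contrastMaps[
      grep("^subtype", names(bundle$contrastMaps))]
    allMap <- bundle$contrastMaps$allPatients
    epi <- list()
    for (nm in names(subMaps)) {
      cc <- couplingAndCompare(subMaps[[nm]], allMap, cge)
      # ascending ranks fit decrease-dominated maps; flip otherwise
      dirn <- if (median(subMaps[[nm]]$t) <= 0) "ascending" else
        "descending"
      et <- epicenterTest(cge, subMaps[[nm]], direction = dirn,
                          nPerm = config$nPermEpicenter,
                          alpha = config$alphaEpicenter,
                          seed = .childSeed(seed, paste0("epi", nm)))
      epi[[nm]] <- list(coupling = cc, epicenters = et)
    }
    bundle$epicenter <- epi
    bundle$completed <- c(bundle$completed, "epicenter")
  }

  bundle$summary <- .bundleSummary(bundle)
  class(bundle) <- "ReportBundle"
  if (!is.null(config$outDir)) .writeBundle(bundle, config$outDir)
  bundle
}

.bundleSummary <- function(bundle) {
  s <- list(seed = bundle$config$seed, completed = bundle$completed)
  om <- bundle$overlapMaps
  if (!is.null(om))
    s$overlap <- list(pctAnyPos = om$pctAnyPos, pctAnyNeg = om$pctAnyNeg,
                      maxOverlapPct = om$maxOverlapPct)
  if (!is.null(bundle$cvKfold)) {
    s$meanSMSEKfold <- bundle$cvKfold$meanSMSE
    s$meanSMSELoso <- bundle$cvLoso$meanSMSE
  }
  if (!is.null(bundle$sigclust))
    s$sigclustP <- sigClustP(bundle$sigclust)
  if (!is.null(bundle$subtypes)) {
    s$kSelected <- kSelected(bundle$subtypes)
    s$clusterSizes <- as.integer(table(subtypeLabels(bundle$subtypes)))
    s$meanSubsampleARI <- bundle$stabilitySubsample$meanARI
    s$meanLosoARI <- bundle$stabilityLoso$meanARI
  }
  if (!is.null(bundle$subtypeMapCorrelation))
    s$subtypeMapR <- bundle$subtypeMapCorrelation$r
  if (!is.null(bundle$molecular))
    s$molecular <- lapply(bundle$molecular, function(m)
      list(adjustedR2 = m$fit$adjustedR2, permutationP = m$fit$permutationP,
           excitatoryShare = m$classes$excitatoryShare))
  if (!is.null(bundle$epicenter))
    s$epicenter <- lapply(bundle$epicenter, function(e)
      list(r = e$coupling$rSubtype, rAll = e$coupling$rAll,
           steigerZ = e$coupling$steigerZ,
           nEpicenters = length(epicenterRegions(e$epicenters))))
  s
}

.writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGMVExperiment(bundle$cohort, dir)
  if (!is.null(bundle$combatModel))
    writeCombatModel(bundle$combatModel, file.path(dir, "combat.json"))
  if (!is.null(bundle$deviations))
    write.table(data.frame(participant_id = rownames(bundle$deviations),
                           bundle$deviations, check.names = FALSE),
                file.path(dir, "deviations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$subtypes))
    write.table(data.frame(participant_id =
                             names(subtypeLabels(bundle$subtypes)),
                           subtype = subtypeLabels(bundle$subtypes)),
                file.path(dir, "subtypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$contrastMaps))
    for (nm in names(bundle$contrastMaps))
      writeContrastMap(bundle$contrastMaps[[nm]],
                       file.path(dir, paste0("contrast_", nm, ".tsv")))
  if (!is.null(bundle$cge))
    writeCGE(bundle$cge, file.path(dir, "cge.tsv"))
  if (!is.null(bundle$epicenter))
    for (nm in names(bundle$epicenter))
      write.table(epicenterTable(bundle$epicenter[[nm]]$epicenters),
                  file.path(dir, paste0("epicenter_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  .writeJSON(bundle$summary, file.path(dir, "summary.json"))
  invisible(dir)
}

#' Compare two pipeline runs under different parcellations
#'
#' Quantifies reproducibility across atlases: the adjusted Rand index
#' between the two subtype labelings (after label alignment) and the
#' Spearman correlation between corresponding subtype abnormality maps.
#' `regionCorrespondence` maps each region of bundle A onto a region id
#' of bundle B (several A regions may map to one B region; A maps are
#' averaged within groups before correlation).
#'
#' @param bundleA,bundleB `ReportBundle`s clustering the same subjects.
#' @param regionCorrespondence named vector: A-region id -> B-region id.
#' @return list with `labelARI` and `mapCorrelation` (per subtype map).
#' @export
atlasSwapCompare <- function(bundleA, bundleB, regionCorrespondence) {
  la <- subtypeLabels(bundleA$subtypes)
  lb <- subtypeLabels(bundleB$subtypes)
  if (!identical(names(la), names(lb)))
    stop("the two bundles cluster different subjects", call. = FALSE)
  aligned <- alignClusterLabels(la, lb)
  ari <- adjustedRandIndex(la, lb)
  mapsA <- bundleA$contrastMaps[grep("^subtype",
                                     names(bundleA$contrastMaps))]
  mapsB <- bundleB$contrastMaps[grep("^subtype",
                                     names(bundleB$contrastMaps))]
  rho <- setNames(rep(NA_real_, length(mapsA)), names(mapsA))
  for (nm in names(mapsA)) {
    # map subtype identity of A onto B's labeling before pairing maps
    kA <- as.integer(sub("subtype", "", nm))
    kB <- unique(aligned[la == kA])[1]
    nmB <- paste0("subtype", kB)
    if (!nmB %in% names(mapsB)) next
    a <- setNames(mapsA[[nm]]$t, mapsA[[nm]]$region)
    b <- setNames(mapsB[[nmB]]$t, mapsB[[nmB]]$region)
    grp <- regionCorrespondence[names(a)]
    agg <- tapply(a, grp, mean)
    common <- intersect(names(agg), names(b))
    rho[nm] <- cor(agg[common], b[common], method = "spearman")
  }
  list(labelARI = ari, mapCorrelation = rho)
}
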