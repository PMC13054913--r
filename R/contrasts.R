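#' Covariate-adjusted regional group contrast
#'
#' Per region, ordinary least squares of GMV on
#' `[intercept, group, age, sex, site dummies]`; the reported statistic is
#' the t of the group coefficient (patients minus controls), unthresholded
#' - this regional t-map is the abnormality map consumed by the molecular
#' and epicenter stages. Significance is Bonferroni-corrected across
#' regions at family alpha.
#'
#' @param x a [GMVExperiment-class] or a subjects x regions matrix.
#' @param group logical/factor group indicator (for a `GMVExperiment` the
#'   default contrasts all patients vs HC; pass a logical subset to
#'   contrast one subtype vs HC).
#' @param covariates for a matrix: data.frame with `age`, `sex` and
#'   optionally `site` (dummy-coded, first site lexicographically is the
#'   reference). Sites entirely within one group are dropped from the
#'   design with a warning (their dummy is collinear with group).
#' @param alpha family-wise alpha for the Bonferroni mask.
#' @param subset optional logical/index vector of subjects to use (e.g.
#'   HCs plus one subtype).
#' @return a `ContrastMap` data.frame: `region`, `t`, `p`, `df`,
#'   `significant`, plus attributes `contrast` and `alpha`.
#' @export
setGeneric("glmGroupContrast",
           function(x, group, covariates = NULL, alpha = 0.05,
                    subset = NULL) standardGeneric("glmGroupContrast"))

#' @rdname glmGroupContrast
#' @export
setMethod("glmGroupContrast", "GMVExperiment",
  function(x, group = NULL, covariates = NULL, alpha = 0.05,
           subset = NULL) {
    pt <- participants(x)
    if (is.null(group)) group <- pt$group != "HC"
    m <- gmvMatrix(x)
    cov <- pt[, c("age", "sex", "site")]
    if (!is.null(subset)) {
      m <- m[subset, , drop = FALSE]
      cov <- cov[subset, , drop = FALSE]
      group <- group[subset]
    }
    glmGroupContrast(m, group, cov, alpha)
  })

#' @rdname glmGroupContrast
#' @export
setMethod("glmGroupContrast", "matrix",
  function(x, group, covariates = NULL, alpha = 0.05, subset = NULL) {
    group <- as.numeric(as.logical(group))
    if (length(unique(group)) < 2)
      stop("both groups must be non-empty", call. = FALSE)
    X <- cbind(intercept = 1, group = group)
    if (!is.null(covariates)) {
      cv <- as.data.frame(covariates)
      for (v in intersect(c("age", "sex"), colnames(cv)))
        X <- cbind(X, setNames(data.frame(cv[[v]]), v))
      if ("site" %in% colnames(cv)) {
        site <- factor(as.character(cv$site))   # reference: first site
        if (nlevels(site) > 1) {
          # a site entirely within one group has a dummy collinear with
          # the group column; drop that dummy, keep the subjects
          spread <- tapply(group, site, function(g) length(unique(g)))
          confounded <- names(spread)[spread == 1]
          if (length(confounded))
            warning("site(s) entirely within one group dropped from the ",
                    "design: ", paste(confounded, collapse = ", "))
          dm <- model.matrix(~ site)[, -1, drop = FALSE]
          dm <- dm[, !(colnames(dm) %in% paste0("site", confounded)),
                   drop = FALSE]
          if (ncol(dm)) X <- cbind(X, dm)
        }
      }
    }
    X <- as.matrix(X)
    qrx <- qr(X)
    if (qrx$rank < ncol(X))
      stop("design not full rank after dummy coding", call. = FALSE)
    n <- nrow(X); dfRes <- n - qrx$rank
    XtXinv <- chol2inv(qr.R(qrx))
    gIdx <- 2L
    tvals <- pvals <- numeric(ncol(x))
    for (g in seq_len(ncol(x))) {
      fit <- qr.coef(qrx, x[, g])
      res <- x[, g] - X %*% fit
      s2 <- sum(res^2) / dfRes
      se <- sqrt(s2 * XtXinv[gIdx, gIdx])
      tvals[g] <- fit[gIdx] / se
      pvals[g] <- 2 * pt(-abs(tvals[g]), dfRes)
    }
    regions <- colnames(x)
    if (is.null(regions)) regions <- sprintf("R%03d", seq_len(ncol(x)))
    out <- data.frame(region = regions, t = tvals, p = pvals, df = dfRes,
                      significant = pvals <= alpha / ncol(x))
    attr(out, "alpha") <- alpha
    attr(out, "contrast") <- "group (coded 1) minus reference"
    class(out) <- c("ContrastMap", "data.frame")
    out
  })

#' Spatial correlation between two regional maps
#'
#' Pearson correlation across regions between two t-maps (the statistic
#' used to compare subtype abnormality patterns), with a t-distribution p
#' on `n_regions - 2` degrees of freedom.
#'
#' @param mapA,mapB `ContrastMap` data.frames or numeric vectors over the
#'   same regions.
#' @return list with `r`, `p`, `n`.
#' @export
spatialCorrelation <- function(mapA, mapB) {
  a <- if (is.data.frame(mapA)) mapA$t else as.numeric(mapA)
  b <- if (is.data.frame(mapB)) mapB$t else as.numeric(mapB)
  if (length(a) != length(b)) stop("maps cover different region sets")
  if (sd(a) == 0 || sd(b) == 0) stop("constant map: correlation undefined")
  n <- length(a)
  r <- cor(a, b)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Demographic and clinical comparison between subtypes
#'
#' Two-sample t-tests for continuous variables and chi-square tests for
#' categorical ones, between the two largest subtypes (or all pairs when
#' `pairwise = FALSE` only the first two are compared). Expected cell
#' counts < 5 flag the chi-square with a warning (the test is still
#' reported).
#'
#' @param participants participants data.frame.
#' @param labels subtype labels aligned with `participants` rows (patients
#'   only or full cohort; non-patient rows may be NA).
#' @param variables columns to compare (default: every column except ids
#'   and design columns).
#' @return data.frame with `variable`, `type`, `statistic`, `df`, `p`.
#' @export
compareDemographics <- function(participants, labels,
                                variables = NULL) {
  keep <- !is.na(labels)
  pt <- participants[keep, , drop = FALSE]
  lab <- labels[keep]
  lev <- sort(unique(lab))
  if (length(lev) < 2) stop("need >= 2 subtypes", call. = FALSE)
  if (length(lev) > 2) {
    lev <- names(sort(table(lab), decreasing = TRUE))[1:2]
    pt <- pt[lab %in% lev, , drop = FALSE]
    lab <- lab[lab %in% lev]
  }
  if (is.null(variables))
    variables <- setdiff(colnames(pt),
                         c("participant_id", "site", "group",
                           "subtype_truth"))
  rows <- lapply(variables, function(v) {
    x <- pt[[v]]
    if (is.numeric(x) && length(unique(x)) > 5) {
      tt <- t.test(x[lab == lev[1]], x[lab == lev[2]])
      data.frame(variable = v, type = "t",
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    } else {
      tab <- table(factor(x), factor(lab))
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      if (any(ct$expected < 5))
        warning("variable '", v, "': expected cell count < 5; ",
                "chi-square approximation is weak")
      data.frame(variable = v, type = "chisq",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value)
    }
  })
  do.call(rbind, rows)
}

#' Write a contrast map as TSV
#'
#' @param map a `ContrastMap`.
#' @param path output path.
#' @export
writeContrastMap <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
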