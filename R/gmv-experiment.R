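#' Construct a GMVExperiment
#'
#' @param gmv numeric matrix of regional gray matter volumes, subjects x
#'   regions (the orientation of the on-disk TSV dialect). Stored internally
#'   as regions x subjects.
#' @param participants data.frame with one row per subject and at least
#'   `participant_id`, `age`, `sex` (0 = male, 1 = female), `site`, `group`
#'   (`"HC"` for controls). Extra columns (e.g. `subtype_truth`, HAMD) are
#'   kept.
#' @param metadata optional list stored in the object metadata (e.g. the
#'   simulation ground truth).
#' @return a [GMVExperiment-class] object.
#' @examples
#' cohort <- generateCohort(cohortConfig(nSites = 2, nHCPerSite = 10,
#'                                       nPatPerSite = 10, nRegions = 12,
#'                                       seed = 1))
#' cohort
#' @export
GMVExperiment <- function(gmv, participants, metadata = list()) {
  gmv <- as.matrix(gmv)
  if (nrow(gmv) != nrow(participants))
    stop("gmv must have one row per participants row")
  if (is.null(rownames(gmv)))
    rownames(gmv) <- as.character(participants$participant_id)
  if (is.null(colnames(gmv)))
    colnames(gmv) <- sprintf("R%03d", seq_len(ncol(gmv)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(gmv = t(gmv)),
    colData = S4Vectors::DataFrame(participants,
                                   row.names = rownames(gmv)),
    metadata = metadata)
  methods::new("GMVExperiment", se)
}

#' @describeIn GMVExperiment subjects x regions GMV matrix.
#' @param x a `GMVExperiment`.
#' @export
gmvMatrix <- function(x) {
  stopifnot(methods::is(x, "GMVExperiment"))
  t(SummarizedExperiment::assay(x, "gmv"))
}

#' @describeIn GMVExperiment participants table as a data.frame.
#' @export
participants <- function(x) {
  stopifnot(methods::is(x, "GMVExperiment"))
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn GMVExperiment simulation ground truth (NULL for real data).
#' @export
groundTruth <- function(x) {
  S4Vectors::metadata(x)$groundTruth
}

setMethod("show", "GMVExperiment", function(object) {
  pt <- participants(object)
  cat("GMVExperiment:", nrow(object), "regions x", ncol(object),
      "subjects\n")
  cat("  sites:", length(unique(pt$site)),
      " | HC:", sum(pt$group == "HC"),
      " patients:", sum(pt$group != "HC"), "\n")
  if (!is.null(groundTruth(object)))
    cat("  carries simulation ground truth\n")
  invisible(NULL)
})

#' Read / write the tabular cohort dialect
#'
#' The on-disk dialect is TSV: the region matrix has a leading
#' `participant_id` column followed by one column per region; the
#' participants table has columns `participant_id`, `age`, `sex`, `site`,
#' `group` (plus any extras).
#'
#' @param matrixPath,participantsPath file paths.
#' @return `readGMVExperiment`: a [GMVExperiment-class].
#' @export
readGMVExperiment <- function(matrixPath, participantsPath) {
  pt <- read.delim(participantsPath, sep = "\t", check.names = FALSE)
  rm <- read.delim(matrixPath, sep = "\t", check.names = FALSE)
  if (colnames(rm)[1] != "participant_id")
    stop("region matrix must start with a participant_id column")
  m <- as.matrix(rm[, -1, drop = FALSE])
  rownames(m) <- as.character(rm$participant_id)
  idx <- match(as.character(pt$participant_id), rownames(m))
  if (anyNA(idx)) stop("participants without matching matrix rows")
  GMVExperiment(m[idx, , drop = FALSE], pt)
}

#' @rdname readGMVExperiment
#' @param x a `GMVExperiment`.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return `writeGMVExperiment`: invisibly, the two file paths.
#' @export
writeGMVExperiment <- function(x, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- gmvMatrix(x)
  mp <- file.path(dir, paste0(prefix, "_gmv.tsv"))
  pp <- file.path(dir, paste0(prefix, "_participants.tsv"))
  write.table(data.frame(participant_id = rownames(m), m,
                         check.names = FALSE),
              mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(participants(x), pp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix = mp, participants = pp))
}
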