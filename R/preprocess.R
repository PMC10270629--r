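#' Construct an ExpressionCohort
#'
#' @param counts gene x sample matrix of non-negative values (raw read
#'   counts for a new cohort).
#' @param lengths named numeric vector of gene lengths in bp (or a vector
#'   in row order).
#' @param groups named character/factor of sample group labels (or a
#'   vector in column order); two-group analyses expect exactly two levels.
#' @param stage \code{"raw"} (default) or \code{"normalized"}.
#' @return an \linkS4class{ExpressionCohort}.
#' @export
expressionCohort <- function(counts, lengths, groups, stage = "raw") {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(counts),
                             if (stage == "raw") "counts" else "normalized"),
    rowData = S4Vectors::DataFrame(length = as.numeric(lengths),
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(counts)))
  S4Vectors::metadata(se)$stage <- stage
  new("ExpressionCohort", se)
}

#' @rdname expressionCohort
#' @param x an \linkS4class{ExpressionCohort}.
#' @export
cohortStage <- function(x) S4Vectors::metadata(x)$stage

#' @rdname expressionCohort
#' @export
cohortGroups <- function(x)
  stats::setNames(as.character(SummarizedExperiment::colData(x)$group),
                  colnames(x))

#' @rdname expressionCohort
#' @export
geneLengths <- function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$length, rownames(x))

#' Filter lowly expressed genes
#'
#' Keeps genes that reach at least \code{minCount} read counts in at least
#' a \code{minFraction} share of samples (default: at least 5 counts in at
#' least 25\% of samples); everything else is considered not reliably
#' expressed and removed. The sample set is unchanged.
#'
#' @param cohort a raw-stage \linkS4class{ExpressionCohort}.
#' @param minCount count threshold (default 5).
#' @param minFraction minimum fraction of samples reaching it (default
#'   0.25).
#' @return the filtered cohort.
#' @export
filterLowExpressed <- function(cohort, minCount = 5, minFraction = 0.25) {
  if (cohortStage(cohort) != "raw")
    stop("filtering applies to raw counts")
  a <- SummarizedExperiment::assay(cohort, "counts")
  keep <- rowMeans(a >= minCount) >= minFraction
  if (!any(keep))
    stop("every gene was filtered out; review minCount/minFraction ",
         "against the sequencing depth")
  cohort[keep, ]
}

#' Normalize a filtered count matrix
#'
#' Between-sample normalization by median-of-ratios size factors (the
#' DESeq2 estimator: for each sample, the median over all-positive genes of
#' the count divided by that gene's geometric mean across samples),
#' followed by gene-length adjustment to counts per kilobase and a
#' log2(x + 1) transform.
#'
#' @param cohort a raw-stage (filtered) \linkS4class{ExpressionCohort}.
#' @return a normalized-stage cohort whose assay \code{"normalized"} holds
#'   \code{log2(count / sizeFactor / (length/1000) + 1)}.
#' @export
normalizeCohort <- function(cohort) {
  if (cohortStage(cohort) != "raw")
    stop("cohort is already normalized")
  a <- SummarizedExperiment::assay(cohort, "counts")
  sf <- tryCatch(DESeq2::estimateSizeFactorsForMatrix(a),
                 error = function(e)
                   stop("size factors are undefined (no gene with positive ",
                        "counts in every sample): ", conditionMessage(e)))
  kb <- geneLengths(cohort) / 1000
  norm <- log2(sweep(sweep(a, 2, sf, "/"), 1, kb, "/") + 1)
  out <- expressionCohort(norm, geneLengths(cohort), cohortGroups(cohort),
                          stage = "normalized")
  S4Vectors::metadata(out)$sizeFactors <- sf
  out
}

#' Read an expression cohort from TSV files
#'
#' @param countsPath TSV with genes in rows (first column = gene id) and
#'   samples in columns.
#' @param lengthsPath two-column TSV: gene id, length in bp.
#' @param groupsPath two-column TSV: sample id, group label.
#' @return a raw-stage \linkS4class{ExpressionCohort}.
#' @export
readCohort <- function(countsPath, lengthsPath, groupsPath) {
  counts <- as.matrix(utils::read.table(countsPath, sep = "\t", header = TRUE,
                                        row.names = 1, check.names = FALSE))
  len <- utils::read.table(lengthsPath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  grp <- utils::read.table(groupsPath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expressionCohort(counts,
                   stats::setNames(len[[2]], len[[1]]),
                   stats::setNames(grp[[2]], grp[[1]]))
}

#' Write a cohort's expression matrix as TSV
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param path output path.
#' @export
writeCohortMatrix <- function(cohort, path) {
  a <- SummarizedExperiment::assay(cohort, 1L)
  df <- data.frame(gene = rownames(a), a, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
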