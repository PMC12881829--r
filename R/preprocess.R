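#' Filter cells by number of detected genes
#'
#' Removes cells expressing fewer than \code{minGenes} genes, where a gene
#' counts as expressed when its value is strictly positive. The comparison
#' is strict on the low side ("fewer than"): a cell with exactly
#' \code{minGenes} detected genes is retained. Cell order is preserved.
#'
#' @param m an \linkS4class{ExpressionMatrix} in \code{raw_counts} state.
#' @param minGenes minimum number of detected genes (default 200).
#' @return The filtered ExpressionMatrix.
#' @export
filterCells <- function(m, minGenes = 200L) {
  .checkState(m, "raw_counts", "filterCells")
  detected <- rowSums(m@values > 0)
  keep <- detected >= minGenes
  if (!any(keep))
    stop("filterCells removed every cell; review the minGenes threshold (",
         minGenes, ")")
  m[keep, ]
}

#' Filter genes by detection fraction
#'
#' Retains genes detected (value > 0) in at least
#' \code{minCellFraction * nCells} cells, where \code{nCells} is the current
#' (post cell-filter) cell count. The required count is the real-valued
#' product, not its ceiling: a gene detected in exactly
#' \code{minCellFraction * nCells} cells is retained. Gene order is
#' preserved.
#'
#' @param m an \linkS4class{ExpressionMatrix} in \code{raw_counts} state.
#' @param minCellFraction minimum detection fraction (default 0.001).
#' @return The filtered ExpressionMatrix.
#' @export
filterGenes <- function(m, minCellFraction = 0.001) {
  .checkState(m, "raw_counts", "filterGenes")
  nDetected <- colSums(m@values > 0)
  keep <- nDetected >= minCellFraction * nrow(m@values)
  if (!any(keep))
    stop("filterGenes removed every gene; review the minCellFraction ",
         "threshold (", minCellFraction, ")")
  m[, keep]
}

#' Scale each cell to a common total count
#'
#' Rescales every cell so its values sum to \code{targetSum} (default
#' 10000), preserving within-cell proportions.
#'
#' Normalization leaves the \code{raw_counts} state (values are no longer
#' integers), so the result is flagged \code{normalized_log}; the state
#' guard prevents re-normalizing or re-filtering the output.
#'
#' @param m an \linkS4class{ExpressionMatrix} in \code{raw_counts} state
#'   with strictly positive cell totals.
#' @param targetSum the common post-normalization total.
#' @return The rescaled ExpressionMatrix.
#' @export
normalizeTotal <- function(m, targetSum = 10000) {
  .checkState(m, "raw_counts", "normalizeTotal")
  totals <- rowSums(m@values)
  if (any(totals <= 0)) {
    bad <- rownames(m@values)[totals <= 0]
    stop("cells with zero total count (should have been filtered): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  v <- m@values * (targetSum / totals)
  new("ExpressionMatrix", values = v, cellNames = m@cellNames,
      state = "normalized_log")  # non-integer intermediate; see logTransform
}

#' Log-transform expression values
#'
#' Applies the natural-log transform \code{log(1 + x)} elementwise and marks
#' the matrix \code{normalized_log}.
#'
#' @param m an \linkS4class{ExpressionMatrix} with non-negative values.
#' @return The transformed ExpressionMatrix.
#' @export
logTransform <- function(m) {
  if (any(m@values < 0)) stop("logTransform requires non-negative values")
  new("ExpressionMatrix", values = log1p(m@values),
      cellNames = m@cellNames, state = "normalized_log")
}

#' Full preprocessing pipeline
#'
#' Runs cell filtering, gene filtering, total-count normalization and
#' log1p transformation in that order. The gene-detection fraction is
#' computed against the post-cell-filter cell count.
#'
#' @param m an \linkS4class{ExpressionMatrix} of raw counts.
#' @param config a \linkS4class{RunConfig} supplying the thresholds, or
#'   NULL to use the individual arguments.
#' @param minGenes,minCellFraction,targetSum thresholds used when
#'   \code{config} is NULL.
#' @param restrictGenes optional character vector restricting the matrix
#'   to these genes (applied after filtering, before normalization).
#'   Highly-variable-gene selection is deliberately not reimplemented
#'   here: compute the gene list with standard tooling (e.g. scran or
#'   Seurat) and pass it in.
#' @return A preprocessed ExpressionMatrix in \code{normalized_log} state.
#' @examples
#' sp <- syntheticSpec(nCellsPerType = 20, seed = 7)
#' d <- generateDataset(sp)
#' pp <- preprocessCells(d$matrix, minGenes = 10)
#' @export
preprocessCells <- function(m, config = NULL, minGenes = 200L,
                            minCellFraction = 0.001, targetSum = 10000,
                            restrictGenes = NULL) {
  if (!is.null(config)) {
    stopifnot(is(config, "RunConfig"))
    minGenes <- config@minGenes
    minCellFraction <- config@minCellFraction
    targetSum <- config@targetSum
  }
  m <- filterCells(m, minGenes)
  m <- filterGenes(m, minCellFraction)
  if (!is.null(restrictGenes)) {
    keep <- geneIds(m) %in% restrictGenes
    if (!any(keep)) stop("restrictGenes shares no genes with the matrix")
    m <- m[, keep]
  }
  m <- normalizeTotal(m, targetSum)
  logTransform(m)
}

.checkState <- function(m, state, op) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (m@state != state)
    stop(op, " requires state=", state, " but the matrix is ", m@state)
  invisible(TRUE)
}
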