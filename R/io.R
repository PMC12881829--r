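#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: each line is
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate genes
#' within a line are removed; trailing whitespace and blank lines are
#' ignored.
#'
#' @param path GMT file path.
#' @return A \linkS4class{PathwayCollection}.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- sub("[ \t\r]+$", "", readLines(path, warn = FALSE))
  keep <- nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", lineNo[i],
           ": expected name, description and at least one gene")
    id <- fields[1]
    if (id %in% names(sets))
      stop("duplicate pathway id '", id, "' at GMT line ", lineNo[i])
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("empty gene list at GMT line ", lineNo[i])
    sets[[id]] <- genes
  }
  PathwayCollection(sets)
}

#' Write gene sets to a GMT file
#'
#' @param pathwayCollection a \linkS4class{PathwayCollection}.
#' @param path output path.
#' @param descriptions optional per-pathway description column (defaults
#'   to \code{"na"}).
#' @export
writeGMT <- function(pathwayCollection, path, descriptions = NULL) {
  sets <- pathways(pathwayCollection)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix
#'
#' Supported formats:
#' \describe{
#'   \item{csv}{dense CSV, cells as rows: first column \code{cell_id},
#'     an optional \code{nameColumn} column of cell names, remaining
#'     columns one per gene.}
#'   \item{mtx_dir}{a directory with \code{matrix.mtx} (MatrixMarket,
#'     genes x cells), \code{genes.tsv} (gene id per line, first field)
#'     and \code{barcodes.tsv} (cell barcode per line; an optional second
#'     field holds the cell name).}
#'   \item{h5ad}{AnnData HDF5, converted through the bundled Python
#'     bridge (requires \code{python} with \code{anndata} on the PATH);
#'     cell names are taken from the \code{nameColumn} obs column when
#'     present.}
#' }
#' The processing state is inferred: \code{raw_counts} iff every value is
#' a non-negative integer within 1e-6, else \code{normalized_log}.
#'
#' @param path file (csv, h5ad) or directory (mtx_dir) path.
#' @param format one of \code{"csv"}, \code{"mtx_dir"}, \code{"h5ad"}.
#' @param nameColumn name of the cell-name annotation column.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path, format = c("csv", "mtx_dir", "h5ad"),
                           nameColumn = "cell_name") {
  format <- match.arg(format)
  switch(format,
         csv = .readExpressionCsv(path, nameColumn),
         mtx_dir = .readExpressionMtx(path),
         h5ad = .readExpressionH5ad(path, nameColumn))
}

.readExpressionCsv <- function(path, nameColumn) {
  if (!file.exists(path)) stop("CSV file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(df) || nrow(df) == 0) stop("empty CSV expression file")
  cellIds <- as.character(df[[1]])
  df <- df[-1]
  nms <- character(0)
  if (nameColumn %in% names(df)) {
    nms <- as.character(df[[nameColumn]])
    df <- df[names(df) != nameColumn]
  }
  vals <- as.matrix(df)
  if (!is.numeric(vals)) stop("non-numeric entries in expression CSV")
  rownames(vals) <- cellIds
  ExpressionMatrix(vals, cellNames = nms, state = "auto")
}

.readExpressionMtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  gf <- file.path(dir, "genes.tsv")
  bf <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, gf, bf))
    if (!file.exists(f)) stop("missing MTX component: ", f)
  m <- as.matrix(Matrix::readMM(mtx))      # genes x cells
  genes <- utils::read.delim(gf, header = FALSE, stringsAsFactors = FALSE)
  bars <- utils::read.delim(bf, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m))
    stop("genes.tsv has ", nrow(genes), " entries but the matrix has ",
         nrow(m), " gene rows")
  if (nrow(bars) != ncol(m))
    stop("barcodes.tsv has ", nrow(bars), " entries but the matrix has ",
         ncol(m), " cell columns")
  vals <- t(m)
  rownames(vals) <- as.character(bars[[1]])
  colnames(vals) <- as.character(genes[[1]])
  nms <- if (ncol(bars) >= 2) as.character(bars[[2]]) else character(0)
  ExpressionMatrix(vals, cellNames = nms, state = "auto")
}

#' Write an expression matrix
#'
#' Inverse of \code{\link{readExpression}}; values are serialized at full
#' double precision (\code{\%.17g}) so a write/read round trip is
#' bit-exact for every format.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param path output file (csv, h5ad) or directory (mtx_dir).
#' @param format one of \code{"csv"}, \code{"mtx_dir"}, \code{"h5ad"}.
#' @param nameColumn column name under which cell names are stored.
#' @export
writeExpression <- function(m, path, format = c("csv", "mtx_dir", "h5ad"),
                            nameColumn = "cell_name") {
  stopifnot(is(m, "ExpressionMatrix"))
  format <- match.arg(format)
  switch(format,
         csv = .writeExpressionCsv(m, path, nameColumn),
         mtx_dir = .writeExpressionMtx(m, path),
         h5ad = .writeExpressionH5ad(m, path, nameColumn))
  invisible(path)
}

.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  ifelse(x == round(x) & abs(x) < 1e15, sprintf("%d", as.integer(round(x))), out)
}

.writeExpressionCsv <- function(m, path, nameColumn) {
  vals <- exprValues(m)
  header <- c("cell_id",
              if (length(cellNames(m))) nameColumn,
              colnames(vals))
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(rownames(vals)[i],
            if (length(cellNames(m))) cellNames(m)[i],
            .fmtNum(vals[i, ])), collapse = ",")
  }, "")
  writeLines(c(paste(header, collapse = ","), body), path)
}

# MatrixMarket with full precision; genes x cells orientation.
.writeMtx <- function(vals, path) {
  nz <- which(vals != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(vals), ncol(vals), nrow(nz))), con)
  if (nrow(nz))
    writeLines(sprintf("%d %d %s", nz[, 1], nz[, 2],
                       .fmtNum(vals[nz])), con)
}

.writeExpressionMtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- t(exprValues(m))                 # genes x cells
  .writeMtx(vals, file.path(dir, "matrix.mtx"))
  writeLines(rownames(vals), file.path(dir, "genes.tsv"))
  bars <- colnames(vals)
  if (length(cellNames(m)))
    bars <- paste(bars, cellNames(m), sep = "\t")
  writeLines(bars, file.path(dir, "barcodes.tsv"))
}

# ---- h5ad via the bundled Python/anndata bridge -------------------------

.h5adBridge <- function() {
  script <- system.file("python", "h5ad_bridge.py", package = "scPathAlign")
  if (!nzchar(script)) stop("h5ad bridge script not found in the package")
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("h5ad support requires a python interpreter with anndata on PATH")
  list(python = unname(py), script = script)
}

.runBridge <- function(args) {
  b <- .h5adBridge()
  out <- suppressWarnings(
    system2(b$python, c(b$script, args), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("h5ad bridge failed: ", paste(out, collapse = "\n"))
  invisible(out)
}

.readExpressionH5ad <- function(path, nameColumn) {
  if (!file.exists(path)) stop("h5ad file not found: ", path)
  tmp <- tempfile("h5ad_x_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  .runBridge(c("export", shQuote(path), shQuote(tmp), shQuote(nameColumn)))
  m <- .readExpressionMtx(tmp)
  stateFile <- file.path(tmp, "state.txt")
  if (file.exists(stateFile)) {
    st <- readLines(stateFile, warn = FALSE)[1]
    if (st %in% .EXPR_STATES && st != m@state)
      m <- new("ExpressionMatrix", values = m@values,
               cellNames = m@cellNames, state = st)
  }
  m
}

.writeExpressionH5ad <- function(m, path, nameColumn) {
  tmp <- tempfile("h5ad_x_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  .writeExpressionMtx(m, tmp)
  writeLines(m@state, file.path(tmp, "state.txt"))
  .runBridge(c("import", shQuote(tmp), shQuote(path), shQuote(nameColumn)))
}

# ---- prediction tables --------------------------------------------------

#' Write predictions to a TSV file
#'
#' Columns: \code{cell_id}, \code{predicted_name}, \code{top_similarity},
#' \code{seen_entropy}, \code{ood_flag} (literal \code{true}/\code{false})
#' and \code{final_name}; one row per cell plus a header.
#'
#' @param pred a non-empty \linkS4class{PredictionSet}.
#' @param path output TSV path.
#' @export
writePredictions <- function(pred, path) {
  stopifnot(is(pred, "PredictionSet"))
  df <- predictions(pred)
  if (!nrow(df)) stop("no predictions to write")
  df$ood_flag <- ifelse(df$ood_flag, "true", "false")
  df$top_similarity <- .fmtNum(df$top_similarity)
  df$seen_entropy <- .fmtNum(df$seen_entropy)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV written by \code{\link{writePredictions}}
#'
#' @param path TSV path.
#' @return A data.frame with the prediction columns; \code{ood_flag} is
#'   logical.
#' @export
readPredictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$ood_flag <- df$ood_flag == "true"
  df
}
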