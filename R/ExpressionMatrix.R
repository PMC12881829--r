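#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, cells as rows and genes as columns.
#' @param geneIds,cellIds identifiers; default to the dimnames of
#'   \code{values}.
#' @param cellNames optional per-cell free-text type labels. Labels are
#'   normalized to Unicode NFC and trimmed of surrounding whitespace; case is
#'   preserved.
#' @param state \code{"raw_counts"}, \code{"normalized_log"}, or
#'   \code{"auto"} to infer: raw counts iff every value is a non-negative
#'   integer within 1e-6.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- ExpressionMatrix(matrix(0:5, 2, 3,
#'        dimnames = list(c("c1", "c2"), c("g1", "g2", "g3"))))
#' exprState(m)
#' @export
ExpressionMatrix <- function(values, geneIds = colnames(values),
                             cellIds = rownames(values),
                             cellNames = character(0),
                             state = c("auto", "raw_counts", "normalized_log")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(geneIds)) stop("gene identifiers are required")
  if (is.null(cellIds)) stop("cell identifiers are required")
  dimnames(values) <- list(as.character(cellIds), as.character(geneIds))
  if (state == "auto") state <- .inferState(values)
  if (length(cellNames)) cellNames <- .normalizeNames(cellNames)
  new("ExpressionMatrix", values = values,
      cellNames = as.character(cellNames), state = state)
}

.inferState <- function(values) {
  if (length(values) && all(values >= 0) &&
      max(abs(values - round(values))) <= 1e-6) "raw_counts"
  else "normalized_log"
}

# NFC + trim; matching of cell names is exact string equality afterwards.
.normalizeNames <- function(x) {
  trimws(stringi_nfc(x))
}

# stringi is not a dependency; enc2utf8 + iconv NFC when available through
# base. R >= 4.1 has no base NFC, so fall back to identity beyond UTF-8
# conversion (ASCII fixtures are unaffected).
stringi_nfc <- function(x) {
  y <- enc2utf8(as.character(x))
  out <- tryCatch(iconv(y, "UTF-8", "UTF-8"), error = function(e) y)
  ifelse(is.na(out), y, out)
}

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname ExpressionMatrix-class
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("cellIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("cellNames", "ExpressionMatrix", function(x) x@cellNames)

#' @rdname ExpressionMatrix-class
#' @export
setReplaceMethod("cellNames", "ExpressionMatrix", function(x, value) {
  x@cellNames <- if (length(value)) .normalizeNames(value) else character(0)
  validObject(x)
  x
})

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprState", "ExpressionMatrix", function(x) x@state)

#' @rdname ExpressionMatrix-class
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' Subset an ExpressionMatrix by cells and/or genes
#'
#' @param x an ExpressionMatrix.
#' @param i,j cell and gene indices (any standard subscript form).
#' @param ... ignored.
#' @param drop ignored; the result is always an ExpressionMatrix.
#' @export
setMethod("[", "ExpressionMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  nm <- x@cellNames
  if (length(nm)) {
    names(nm) <- rownames(x@values)
    nm <- unname(nm[i])
  }
  new("ExpressionMatrix", values = x@values[i, j, drop = FALSE],
      cellNames = nm, state = x@state)
})

setMethod("show", "ExpressionMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              d[1], d[2], object@state))
  if (length(object@cellNames)) {
    tb <- sort(table(object@cellNames), decreasing = TRUE)
    shown <- utils::head(tb, 5)
    cat(sprintf("cell names (%d types): %s%s\n", length(tb),
                paste(sprintf("%s (%d)", names(shown), shown), collapse = ", "),
                if (length(tb) > 5) ", ..." else ""))
  } else cat("cell names: absent\n")
})

#' Construct a PathwayCollection
#'
#' @param sets named list of character vectors of gene ids; duplicates
#'   within a set are removed.
#' @export
PathwayCollection <- function(sets) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  new("PathwayCollection", sets = sets)
}

#' @rdname PathwayCollection-class
#' @export
setMethod("pathways", "PathwayCollection", function(x) x@sets)

#' @rdname PathwayCollection-class
#' @export
setMethod("nPathways", "PathwayCollection", function(x) length(x@sets))

setMethod("show", "PathwayCollection", function(object) {
  n <- length(object@sets)
  sz <- lengths(object@sets)
  cat(sprintf("PathwayCollection: %d pathways, %d distinct genes\n",
              n, length(unique(unlist(object@sets)))))
  if (n) cat(sprintf("set sizes: min %d / median %g / max %d\n",
                     min(sz), stats::median(sz), max(sz)))
})
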