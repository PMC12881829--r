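#' Initialize an untrained alignment model
#'
#' Allocates all learnable parameters (gene-embedding table, CLS token,
#' transformer layers, projection heads, built-in text-encoder table and,
#' when \code{classes} is non-empty, the supervised classifier head) from
#' a seeded normal initialization (sd 0.02).
#'
#' @param grouping a \linkS4class{GeneGrouping}; its vocabulary fixes the
#'   gene-embedding table size and gene order.
#' @param trainingNames cell names used to build the text-token vocabulary.
#' @param config a \linkS4class{RunConfig}.
#' @param classes class labels for the supervised head; empty for the
#'   contrastive model.
#' @param adapter optional external text encoder: a function mapping a
#'   character vector of names to a (length x textDim) matrix. When given,
#'   only the text projection is trainable on the text side.
#' @param seed integer initialization seed.
#' @return An untrained \linkS4class{AlignmentModel}.
#' @export
initModel <- function(grouping, trainingNames, config = tinyRunConfig(),
                      classes = character(0), adapter = NULL,
                      seed = config@seed) {
  stopifnot(is(grouping, "GeneGrouping"), is(config, "RunConfig"))
  vocab <- buildVocabulary(trainingNames)
  params <- .withSeed(as.integer(seed),
                      .initParams(config, length(grouping@vocabulary),
                                  length(vocab), length(classes)))
  new("AlignmentModel", params = params, config = config,
      grouping = grouping, textVocab = vocab,
      textKind = if (is.null(adapter)) "builtin" else "adapter",
      adapter = adapter, classes = as.character(classes),
      lossTrace = numeric(0))
}

#' @rdname AlignmentModel-class
#' @export
setMethod("lossTrace", "AlignmentModel", function(x) x@lossTrace)

#' @rdname AlignmentModel-class
#' @export
setMethod("modelConfig", "AlignmentModel", function(x) x@config)

#' @rdname AlignmentModel-class
#' @export
setMethod("modelGrouping", "AlignmentModel", function(x) x@grouping)

setMethod("show", "AlignmentModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "AlignmentModel: D=%d, %d layers, %d tokens (+CLS), text=%s\n",
    cfg@embeddingDim, cfg@nLayers, length(object@grouping@groups),
    object@textKind))
  if (length(object@classes))
    cat(sprintf("supervised head: %d classes\n", length(object@classes)))
  if (length(object@lossTrace))
    cat(sprintf("trained %d steps, loss %.4f -> %.4f\n",
                length(object@lossTrace), object@lossTrace[1],
                object@lossTrace[length(object@lossTrace)]))
  else cat("untrained\n")
})

#' Expression-weighted gene-set embedding
#'
#' Computes the embedding of one gene-set token for one cell:
#' \deqn{Z = \frac{1}{n_{gene}} \sum_{j \in group} x_j G_j}
#' where \eqn{x_j} is the cell's expression of gene j and \eqn{G_j} its
#' embedding row. The average divides by the full group size: genes with
#' zero expression participate as zero contributions, they are not dropped
#' from the denominator.
#'
#' @param profile numeric expression vector for one cell (vocabulary
#'   order).
#' @param group integer indices of the group's genes.
#' @param table the gene-embedding matrix (vocabulary x D).
#' @return A numeric vector of length D.
#' @examples
#' tab <- rbind(c(1, 1), c(5, 5))
#' embedGeneSet(c(2, 0), 1:2, tab)  # (2*(1,1) + 0*(5,5)) / 2 = (1,1)
#' @export
embedGeneSet <- function(profile, group, table) {
  if (!length(group)) stop("gene set must be non-empty")
  x <- as.numeric(profile[group])
  as.numeric(crossprod(x, table[group, , drop = FALSE])) / length(group)
}

#' Build the token sequence for one cell
#'
#' Embeds every gene set of the grouping via \code{\link{embedGeneSet}} and
#' prepends the CLS token, yielding an (M+1) x D matrix. No positional
#' encoding is added: gene-set order carries no biological meaning and the
#' encoder is order-invariant.
#'
#' @param profile named numeric expression vector; names must cover the
#'   grouping vocabulary.
#' @param grouping a \linkS4class{GeneGrouping}.
#' @param table gene-embedding matrix (vocabulary x D).
#' @param cls the learnable CLS vector (defaults to zeros).
#' @return Numeric matrix with the CLS row first.
#' @export
buildTokenSequence <- function(profile, grouping, table,
                               cls = numeric(ncol(table))) {
  stopifnot(is(grouping, "GeneGrouping"))
  if (!is.null(names(profile))) {
    missing <- setdiff(grouping@vocabulary, names(profile))
    if (length(missing))
      stop("profile is missing grouping genes: ",
           paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) ", ..." else "")
    profile <- profile[grouping@vocabulary]
  } else if (length(profile) != length(grouping@vocabulary))
    stop("unnamed profile must have exactly one value per vocabulary gene")
  toks <- t(vapply(grouping@groups,
                   function(g) embedGeneSet(profile, g, table),
                   numeric(ncol(table))))
  rbind(cls, toks, deparse.level = 0)
}

#' Encode cells with the pathway-token transformer
#'
#' Runs the transformer encoder in evaluation mode (no dropout) and
#' returns the CLS-position output for each cell: the pre-projection cell
#' embedding. Cells are processed in chunks to bound memory.
#'
#' @param model an \linkS4class{AlignmentModel}.
#' @param m an \linkS4class{ExpressionMatrix} in \code{normalized_log}
#'   state whose genes match the model's grouping vocabulary.
#' @param chunkSize cells per forward pass.
#' @return A cells x D numeric matrix.
#' @export
encodeCells <- function(model, m, chunkSize = 256L) {
  stopifnot(is(model, "AlignmentModel"))
  .checkState(m, "normalized_log", "encodeCells")
  X <- .alignToVocabulary(m, model@grouping)
  n <- nrow(X)
  out <- matrix(0, n, model@config@embeddingDim)
  for (start in seq(1L, n, by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, n)
    out[idx, ] <- .encForward(model@params, X[idx, , drop = FALSE],
                              model@grouping@groups, model@config)$cls
  }
  rownames(out) <- rownames(X)
  out
}

.alignToVocabulary <- function(m, grouping) {
  X <- exprValues(m)
  missing <- setdiff(grouping@vocabulary, colnames(X))
  if (length(missing))
    stop("expression matrix is missing grouping genes: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ..." else "")
  X[, grouping@vocabulary, drop = FALSE]
}

#' Supervised classification of cells
#'
#' Applies the linear classifier head on top of the encoder's CLS output.
#'
#' @param model an \linkS4class{AlignmentModel} with a trained head (see
#'   \code{\link{trainClassifier}}).
#' @param m a preprocessed \linkS4class{ExpressionMatrix}.
#' @return A list with \code{logits} and \code{probabilities} (cells x
#'   classes) and \code{labels} (argmax class per cell).
#' @export
classifyCells <- function(model, m) {
  if (is.null(model@params$head))
    stop("model has no classifier head; train one with trainClassifier()")
  emb <- encodeCells(model, m)
  logits <- .addB(emb %*% model@params$head$W, model@params$head$b)
  colnames(logits) <- model@classes
  probs <- .softmaxRows(logits)
  colnames(probs) <- model@classes
  list(logits = logits, probabilities = probs,
       labels = model@classes[max.col(logits, ties.method = "first")])
}

#' Save / load a model checkpoint directory
#'
#' The checkpoint directory contains the configuration (YAML), the exact
#' gene grouping (JSON), the text vocabulary, class labels, the loss trace
#' (CSV) and the parameter arrays, so inference never needs the original
#' pathway file.
#'
#' @param model an \linkS4class{AlignmentModel}.
#' @param dir checkpoint directory (created if needed).
#' @export
saveModel <- function(model, dir) {
  stopifnot(is(model, "AlignmentModel"))
  if (model@textKind == "adapter")
    stop("adapter-backed models cannot be serialized; save the builtin form")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeRunConfig(model@config, file.path(dir, "config.yaml"))
  writeGrouping(model@grouping, file.path(dir, "grouping.json"))
  writeLines(model@textVocab, file.path(dir, "text_vocab.txt"))
  writeLines(model@classes, file.path(dir, "classes.txt"))
  utils::write.csv(
    data.frame(step = seq_along(model@lossTrace), loss = model@lossTrace),
    file.path(dir, "loss_trace.csv"), row.names = FALSE)
  saveRDS(model@params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  cfg <- readRunConfig(file.path(dir, "config.yaml"))
  trace <- utils::read.csv(file.path(dir, "loss_trace.csv"))
  new("AlignmentModel",
      params = readRDS(file.path(dir, "params.rds")),
      config = cfg,
      grouping = readGrouping(file.path(dir, "grouping.json")),
      textVocab = readLines(file.path(dir, "text_vocab.txt")),
      textKind = "builtin", adapter = NULL,
      classes = readLines(file.path(dir, "classes.txt")),
      lossTrace = as.numeric(trace$loss))
}
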