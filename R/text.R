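# Built-in cell-name encoder: lowercase word-level tokenization over a
# trainable embedding table with mean pooling. External pretrained language
# models plug in through an adapter callable with the same contract.

.UNK <- "<unk>"

# lowercase, split on non-alphanumerics, drop empties
.tokenizeName <- function(name) {
  toks <- strsplit(tolower(trimws(name)), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Build the text-token vocabulary
#'
#' Tokenizes each name (lowercase, split on non-alphanumeric characters)
#' and returns the sorted unique tokens followed by the shared
#' out-of-vocabulary token \code{"<unk>"}. Deterministic and independent of
#' name order or repetition.
#'
#' @param names character vector of cell-type names.
#' @return Character vector of tokens; the last entry is the UNK token.
#' @examples
#' buildVocabulary(c("B cell", "T cell"))
#' @export
buildVocabulary <- function(names) {
  if (!length(names)) stop("names must be non-empty")
  toks <- sort(unique(unlist(lapply(names, .tokenizeName))))
  c(toks, .UNK)
}

.tokenIdsFor <- function(names, vocab) {
  unkId <- length(vocab)
  lapply(names, function(nm) {
    toks <- .tokenizeName(nm)
    if (!length(toks))
      stop("cell name is empty after tokenization: '", nm, "'")
    ids <- match(toks, vocab)
    ids[is.na(ids)] <- unkId
    ids
  })
}

# forward through the built-in text encoder (pre-projection, N x Dt)
.textEmbed <- function(emb, tokenIds) {
  Dt <- ncol(emb)
  out <- matrix(0, length(tokenIds), Dt)
  for (i in seq_along(tokenIds))
    out[i, ] <- colMeans(emb[tokenIds[[i]], , drop = FALSE])
  out
}

# accumulate gradient into the embedding table
.textEmbedBackward <- function(emb, tokenIds, dOut) {
  dEmb <- matrix(0, nrow(emb), ncol(emb))
  for (i in seq_along(tokenIds)) {
    ids <- tokenIds[[i]]
    contrib <- dOut[i, ] / length(ids)
    for (id in ids) dEmb[id, ] <- dEmb[id, ] + contrib
  }
  dEmb
}

#' Encode cell names into fixed-dimension embeddings
#'
#' For a model with the built-in text encoder, each name is lowercased,
#' split into word tokens, looked up in the trainable token table
#' (out-of-vocabulary tokens share one UNK vector) and mean-pooled. A name
#' composed entirely of tokens seen in training therefore receives a
#' non-UNK embedding even if the full name never occurred — the mechanism
#' behind zero-shot transfer to unseen types. For an adapter model the
#' user-supplied callable is invoked and its output dimension checked.
#'
#' @param names character vector of non-empty names.
#' @param model an \linkS4class{AlignmentModel}.
#' @param project if TRUE (default) the embeddings are mapped through the
#'   text projection head into the shared alignment space.
#' @return A numeric matrix, one row per name.
#' @export
encodeNames <- function(names, model, project = TRUE) {
  stopifnot(is(model, "AlignmentModel"))
  if (!length(names)) stop("names must be non-empty")
  if (any(!nzchar(trimws(names)))) stop("empty cell name")
  names <- .normalizeNames(names)
  if (model@textKind == "adapter") {
    emb <- model@adapter(names)
    if (!is.matrix(emb) || nrow(emb) != length(names) ||
        ncol(emb) != model@config@textDim)
      stop("adapter must return a ", length(names), " x ",
           model@config@textDim, " numeric matrix")
  } else {
    ids <- .tokenIdsFor(names, model@textVocab)
    emb <- .textEmbed(model@params$text$emb, ids)
  }
  if (project)
    emb <- .addB(emb %*% model@params$text$projW, model@params$text$projb)
  rownames(emb) <- names
  emb
}
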