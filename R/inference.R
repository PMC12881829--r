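#' Zero-shot prediction over candidate cell names
#'
#' Encodes every cell and every candidate name, computes cosine
#' similarities in the shared space, and assigns each cell the candidate
#' with the highest similarity (ties broken by candidate-list order).
#' Probabilities are the softmax of the similarities at the model's
#' temperature over the full candidate set; the seen-type entropy is the
#' Shannon entropy (nats) of that distribution restricted to the seen
#' candidates and renormalized. Name embeddings are computed once and
#' reused across cells.
#'
#' Out-of-distribution flags are initialized to FALSE; apply
#' \code{\link{oodThreshold}} and \code{\link{applyOOD}} (or use
#' \code{\link{annotateCells}}) to detect unseen-type cells.
#'
#' @param model a trained \linkS4class{AlignmentModel}.
#' @param m a preprocessed \linkS4class{ExpressionMatrix}.
#' @param candidates unique candidate names (seen and unseen).
#' @param seenSet subset of candidates seen during training; defaults to
#'   all candidates.
#' @return A \linkS4class{PredictionSet}.
#' @export
predictCells <- function(model, m, candidates, seenSet = candidates) {
  stopifnot(is(model, "AlignmentModel"))
  if (!length(candidates)) stop("candidates must be non-empty")
  candidates <- .normalizeNames(candidates)
  seenSet <- .normalizeNames(seenSet)
  if (anyDuplicated(candidates)) stop("candidate names must be unique")
  if (!all(seenSet %in% candidates))
    stop("seenSet must be a subset of candidates")
  emb <- encodeCells(model, m)
  Cp <- .addB(emb %*% model@params$projE$W, model@params$projE$b)
  Tp <- encodeNames(candidates, model)
  sim <- similarityMatrix(Cp, Tp)
  colnames(sim) <- candidates
  rownames(sim) <- cellIds(m)
  probs <- .softmaxRows(sim / model@config@temperature)
  dimnames(probs) <- dimnames(sim)
  seenMask <- candidates %in% seenSet
  ent <- apply(probs, 1L, function(p) seenEntropy(p, seenMask))
  pred <- candidates[max.col(sim, ties.method = "first")]
  new("PredictionSet",
      cellIds = cellIds(m), candidates = candidates, seenSet = seenSet,
      similarities = sim, probabilities = probs, seenEntropy = ent,
      predictedName = pred, oodFlag = rep(FALSE, nrow(sim)),
      finalName = pred, threshold = NA_real_)
}

#' Entropy of the seen-type-restricted prediction distribution
#'
#' Renormalizes the probability vector over the seen candidates and
#' returns its Shannon entropy in nats, with the convention
#' \eqn{0 \log 0 = 0}. Ranges from 0 (probability concentrated on one
#' seen type) to \eqn{\ln n_{seen}} (uniform over seen types).
#'
#' @param probabilities numeric probability vector over all candidates.
#' @param seenMask logical, TRUE for seen candidates.
#' @return Entropy in nats.
#' @examples
#' seenEntropy(rep(0.25, 4), rep(TRUE, 4))  # log(4)
#' @export
seenEntropy <- function(probabilities, seenMask) {
  p <- probabilities[seenMask]
  s <- sum(p)
  if (s <= 0) stop("seen candidates carry zero probability mass")
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy threshold for out-of-distribution detection
#'
#' Returns the second quartile (the median, linear-interpolation quantile
#' convention) of the per-cell seen-type entropies, the data-derived
#' threshold above which a cell is called an unseen type.
#'
#' @param entropies numeric vector of seen-type entropies.
#' @return Scalar threshold.
#' @export
oodThreshold <- function(entropies) {
  if (!length(entropies)) stop("entropies must be non-empty")
  unname(stats::quantile(entropies, 0.5, type = 7))
}

#' Apply an entropy threshold to flag unseen-type cells
#'
#' Cells whose seen-type entropy strictly exceeds the threshold are
#' flagged; their final label becomes the highest-similarity candidate
#' among the unseen candidates. Unflagged cells keep the global
#' argmax-similarity label. Entropy exactly equal to the threshold does
#' not flag.
#'
#' @param pred a \linkS4class{PredictionSet}.
#' @param threshold finite entropy threshold (or +/-Inf).
#' @return The updated \linkS4class{PredictionSet}.
#' @export
applyOOD <- function(pred, threshold) {
  stopifnot(is(pred, "PredictionSet"))
  if (length(threshold) != 1L || is.na(threshold))
    stop("threshold must be a single number")
  flag <- pred@seenEntropy > threshold
  unseenIdx <- which(!(pred@candidates %in% pred@seenSet))
  final <- pred@predictedName
  if (any(flag)) {
    if (!length(unseenIdx))
      stop("cells flagged as unseen but no unseen candidates were offered")
    su <- pred@similarities[flag, unseenIdx, drop = FALSE]
    final[flag] <- pred@candidates[unseenIdx[max.col(su, ties.method = "first")]]
  }
  pred@oodFlag <- flag
  pred@finalName <- final
  pred@threshold <- as.numeric(threshold)
  pred
}

#' One-call zero-shot annotation with OOD detection
#'
#' Runs \code{\link{predictCells}}, derives the median-entropy threshold
#' on these cells with \code{\link{oodThreshold}}, and applies it.
#'
#' @inheritParams predictCells
#' @return A \linkS4class{PredictionSet} with OOD flags set.
#' @export
annotateCells <- function(model, m, candidates, seenSet = candidates) {
  pred <- predictCells(model, m, candidates, seenSet)
  applyOOD(pred, oodThreshold(pred@seenEntropy))
}

#' @describeIn PredictionSet-class results as a data.frame (one row per
#'   cell).
#' @export
setMethod("predictions", "PredictionSet", function(x) {
  data.frame(
    cell_id = x@cellIds,
    predicted_name = x@predictedName,
    top_similarity = x@similarities[cbind(seq_along(x@cellIds),
                                          match(x@predictedName, x@candidates))],
    seen_entropy = x@seenEntropy,
    ood_flag = x@oodFlag,
    final_name = x@finalName,
    stringsAsFactors = FALSE)
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d cells x %d candidates (%d seen)\n",
              length(object@cellIds), length(object@candidates),
              length(object@seenSet)))
  if (!is.na(object@threshold))
    cat(sprintf("OOD threshold %.4f nats; %d cells flagged unseen\n",
                object@threshold, sum(object@oodFlag)))
  else cat("OOD detection not yet applied\n")
})
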