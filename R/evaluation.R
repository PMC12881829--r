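#' Micro and weighted-macro F1 scores
#'
#' Micro-F1 pools true positives, false positives and false negatives over
#' all classes: \code{TP / (TP + (FP + FN) / 2)}; in single-label
#' multi-class classification this equals plain accuracy. Weighted
#' macro-F1 is the mean of per-class F1 scores over the classes present in
#' the truth, weighted by each class's support; classes that appear only
#' among the predictions carry zero weight.
#'
#' @param predicted,truth equal-length character vectors of labels.
#' @param average \code{"micro"} or \code{"weighted_macro"}.
#' @return Scalar score in [0, 1].
#' @examples
#' f1Scores(c("a", "b", "b"), c("a", "b", "a"), "micro")
#' @export
f1Scores <- function(predicted, truth,
                     average = c("micro", "weighted_macro")) {
  average <- match.arg(average)
  if (!length(truth) || length(predicted) != length(truth))
    stop("predicted and truth must be non-empty and of equal length")
  if (average == "micro") {
    classes <- union(unique(truth), unique(predicted))
    tp <- fp <- fn <- 0
    for (cl in classes) {
      tp <- tp + sum(predicted == cl & truth == cl)
      fp <- fp + sum(predicted == cl & truth != cl)
      fn <- fn + sum(predicted != cl & truth == cl)
    }
    return(tp / (tp + (fp + fn) / 2))
  }
  classes <- unique(truth)
  perClass <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    if (tp + fp + fn == 0) 0 else tp / (tp + (fp + fn) / 2)
  }, 1.0)
  support <- vapply(classes, function(cl) sum(truth == cl), 1.0)
  sum(perClass * support) / sum(support)
}

#' Seen/unseen partitioned F1 scores
#'
#' Partitions the cells by whether their TRUE type is in the seen set
#' (partitioning is by truth, never by prediction) and computes micro and
#' weighted-macro F1 within each partition against the full, unrestricted
#' predictions. An empty partition yields NA on that side.
#'
#' @param predicted,truth equal-length label vectors.
#' @param seenSet names regarded as seen during training.
#' @return List with elements \code{seen} and \code{unseen}, each a list
#'   with \code{micro} and \code{weighted_macro}.
#' @export
splitScores <- function(predicted, truth, seenSet) {
  isSeen <- truth %in% seenSet
  score <- function(keep) {
    if (!any(keep)) return(list(micro = NA_real_, weighted_macro = NA_real_))
    list(micro = f1Scores(predicted[keep], truth[keep], "micro"),
         weighted_macro = f1Scores(predicted[keep], truth[keep],
                                   "weighted_macro"))
  }
  list(seen = score(isSeen), unseen = score(!isSeen))
}

#' Harmonic mean of seen and unseen F1
#'
#' \code{2ab / (a + b)}, with the limit convention that the result is 0
#' whenever either score is 0 (including both).
#'
#' @param seenF1,unseenF1 scores in [0, 1].
#' @return The mixed F1 score.
#' @examples
#' mixedF1(0.6, 0.3)  # 0.4
#' @export
mixedF1 <- function(seenF1, unseenF1) {
  if (is.na(seenF1) || is.na(unseenF1)) return(NA_real_)
  if (seenF1 < 0 || unseenF1 < 0) stop("F1 scores must be >= 0")
  if (seenF1 + unseenF1 == 0) return(0)
  2 * seenF1 * unseenF1 / (seenF1 + unseenF1)
}

#' Seen-proportion curve over entropy bins
#'
#' Sorts cells in ascending order of seen-type entropy (ties broken by
#' cell order), partitions them into \code{nBins} contiguous bins whose
#' sizes differ by at most one (the first \code{n mod nBins} bins take the
#' extra cell), and returns the fraction of cells in each bin whose true
#' type is seen. A model whose entropy separates seen from unseen cells
#' yields a high-then-dropping curve.
#'
#' @param entropy per-cell seen-type entropies.
#' @param truthSeen logical, TRUE where the cell's true type is seen.
#' @param nBins number of bins (default 100); requires at least as many
#'   cells as bins.
#' @return Numeric vector of per-bin seen proportions.
#' @export
entropyBinCurve <- function(entropy, truthSeen, nBins = 100L) {
  n <- length(entropy)
  if (length(truthSeen) != n) stop("entropy and truthSeen lengths differ")
  if (n < nBins) stop("need at least as many cells (", n, ") as bins (",
                      nBins, ")")
  ord <- order(entropy)           # stable: ties keep cell order
  base <- n %/% nBins
  extra <- n %% nBins
  sizes <- c(rep(base + 1L, extra), rep(base, nBins - extra))
  bins <- rep(seq_len(nBins), sizes)
  as.numeric(tapply(truthSeen[ord], bins, mean))
}

#' Per-type accuracy
#'
#' For each true type, the fraction of its cells whose final label equals
#' the truth.
#'
#' @param predicted,truth equal-length label vectors.
#' @return Named numeric vector, one entry per true type.
#' @export
perTypeAccuracy <- function(predicted, truth) {
  if (!length(truth)) stop("empty input")
  vapply(split(predicted == truth, truth), mean, 1.0)
}

#' Full evaluation report for a zero-shot annotation run
#'
#' Computes overall micro and weighted-macro F1, the seen/unseen
#' partitioned scores, mixed (harmonic-mean) scores computed micro-with-
#' micro and macro-with-macro, per-type accuracy, and the entropy-bin
#' seen-proportion curve.
#'
#' @param pred a \linkS4class{PredictionSet} (final labels are used).
#' @param truth true type per cell.
#' @param nBins entropy-curve bins; skipped (NULL) when there are fewer
#'   cells than bins.
#' @return A list with components \code{micro_f1},
#'   \code{weighted_macro_f1}, \code{seen}, \code{unseen}, \code{mixed},
#'   \code{per_type_accuracy} and \code{entropy_bins}.
#' @export
evaluateAnnotation <- function(pred, truth, nBins = 100L) {
  stopifnot(is(pred, "PredictionSet"))
  final <- pred@finalName
  if (length(truth) != length(final))
    stop("truth must have one label per cell")
  sp <- splitScores(final, truth, pred@seenSet)
  curve <- if (length(truth) >= nBins)
    entropyBinCurve(pred@seenEntropy, truth %in% pred@seenSet, nBins)
  list(
    micro_f1 = f1Scores(final, truth, "micro"),
    weighted_macro_f1 = f1Scores(final, truth, "weighted_macro"),
    seen = sp$seen,
    unseen = sp$unseen,
    mixed = list(
      micro = mixedF1(sp$seen$micro, sp$unseen$micro),
      weighted_macro = mixedF1(sp$seen$weighted_macro,
                               sp$unseen$weighted_macro)),
    per_type_accuracy = perTypeAccuracy(final, truth),
    entropy_bins = curve)
}
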