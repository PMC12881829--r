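#' Random gene sets of prescribed sizes
#'
#' Draws gene sets of the given sizes from a shuffled copy of the
#' vocabulary (sampling continues cyclically if the sizes sum to more
#' than the vocabulary). Used to build size-matched random groupings for
#' the pathway-vs-random tokenization comparison.
#'
#' @param vocabulary gene identifiers.
#' @param sizes integer set sizes.
#' @param seed integer seed.
#' @return A \linkS4class{PathwayCollection} with sets named
#'   \code{"RND01"}, \code{"RND02"}, ...
#' @export
randomGeneSets <- function(vocabulary, sizes, seed = 1L) {
  vocabulary <- as.character(vocabulary)
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("set sizes must be positive")
  pool <- .withSeed(as.integer(seed), sample(vocabulary))
  need <- sum(sizes)
  if (need > length(pool))
    pool <- rep_len(pool, need)
  bounds <- cumsum(sizes)
  sets <- lapply(seq_along(sizes), function(i) {
    pool[(c(0L, bounds)[i] + 1L):bounds[i]]
  })
  names(sets) <- sprintf("RND%02d", seq_along(sets))
  PathwayCollection(sets)
}

#' Zero-shot annotation experiment on synthetic data
#'
#' Runs the complete study protocol once: generate a synthetic dataset,
#' preprocess it, build the pathway grouping, contrastively train the
#' alignment model on the training split (validation-checkpoint selection
#' with random restarts), predict every test cell against all type names
#' (seen and unseen), and apply median-entropy out-of-distribution
#' detection. Scores are reported both for the raw maximum-similarity
#' predictions and for the OOD-adjusted final labels.
#'
#' @param seed integer seed controlling data generation and training.
#' @param spec the \linkS4class{SyntheticSpec} (defaults to the standard
#'   desk-scale design seeded by \code{seed}).
#' @param config model configuration (default \code{\link{tinyRunConfig}}).
#' @param steps,restarts training protocol (see
#'   \code{\link{trainAlignment}}).
#' @param orphanSetSize random-group size for the tokenizer.
#' @return A list: \code{metrics} (seen/unseen/mixed micro and macro F1 of
#'   the raw zero-shot predictions, mean seen-entropy of truly seen and
#'   truly unseen cells, OOD flagged fraction), \code{report} (the
#'   \code{\link{evaluateAnnotation}} report on the OOD-adjusted labels),
#'   \code{predictions} (the \linkS4class{PredictionSet}), \code{model},
#'   and \code{split}.
#' @export
runZeroShotExperiment <- function(seed = 1L,
                                  spec = syntheticSpec(seed = seed),
                                  config = tinyRunConfig(),
                                  steps = 3000L, restarts = 2L,
                                  orphanSetSize = 110L) {
  d <- generateDataset(spec)
  pp <- preprocessCells(d$matrix)
  gr <- buildGrouping(geneIds(pp), d$pathways, orphanSetSize,
                      seed = spec@seed)
  split <- d$split
  train <- pp[split$train, ]
  val <- pp[split$val, ]
  test <- pp[split$test, ]
  model <- trainAlignment(train, gr, config, steps = steps,
                          seed = as.integer(seed) + 101L,
                          validation = val, restarts = restarts)
  candidates <- vapply(spec@cellTypes, function(ct) ct$name, "")
  pred <- predictCells(model, test, candidates, seenSet = split$seen)
  truth <- cellNames(test)
  isSeen <- truth %in% split$seen
  raw <- splitScores(pred@predictedName, truth, split$seen)
  pred <- applyOOD(pred, oodThreshold(pred@seenEntropy))
  metrics <- list(
    seen_micro_f1 = raw$seen$micro,
    seen_macro_f1 = raw$seen$weighted_macro,
    unseen_micro_f1 = raw$unseen$micro,
    unseen_macro_f1 = raw$unseen$weighted_macro,
    mixed_micro_f1 = mixedF1(raw$seen$micro, raw$unseen$micro),
    mixed_macro_f1 = mixedF1(raw$seen$weighted_macro,
                             raw$unseen$weighted_macro),
    mean_entropy_seen = mean(pred@seenEntropy[isSeen]),
    mean_entropy_unseen = mean(pred@seenEntropy[!isSeen]),
    flagged_fraction = mean(pred@oodFlag),
    chance_level = 1 / length(candidates))
  list(metrics = metrics,
       report = evaluateAnnotation(pred, truth),
       predictions = pred, model = model, split = split)
}

#' Pathway vs size-matched random grouping comparison
#'
#' Trains the alignment model twice on the same synthetic dataset — once
#' with the pathway-informed grouping and once with a size-matched random
#' grouping (random gene sets of the same sizes as the pathways; orphan
#' handling identical) — and reports the seen-type micro-F1 of each. With
#' expression signatures aligned to pathways, the pathway grouping is
#' expected to score at least as well on average.
#'
#' @inheritParams runZeroShotExperiment
#' @param steps training steps per model (a shorter schedule than the
#'   full zero-shot experiment; the comparison is directional).
#' @return Named numeric vector with elements \code{pathway} and
#'   \code{random} (seen micro-F1).
#' @export
runGroupingAblation <- function(seed = 1L,
                                spec = syntheticSpec(seed = seed),
                                config = tinyRunConfig(),
                                steps = 800L, orphanSetSize = 110L) {
  d <- generateDataset(spec)
  pp <- preprocessCells(d$matrix)
  split <- d$split
  train <- pp[split$train, ]
  test <- pp[split$test, ]
  truth <- cellNames(test)
  isSeen <- truth %in% split$seen
  candidates <- vapply(spec@cellTypes, function(ct) ct$name, "")

  grP <- buildGrouping(geneIds(pp), d$pathways, orphanSetSize,
                       seed = spec@seed)
  pwSizes <- lengths(grP@groups[grP@source == "pathway"])
  rndSets <- randomGeneSets(geneIds(pp), pwSizes,
                            seed = as.integer(seed) + 77L)
  grR <- buildGrouping(geneIds(pp), rndSets, orphanSetSize,
                       seed = spec@seed)

  scoreOf <- function(gr) {
    model <- trainAlignment(train, gr, config, steps = steps,
                            seed = as.integer(seed) + 101L)
    pred <- predictCells(model, test, candidates, seenSet = split$seen)
    f1Scores(pred@predictedName[isSeen], truth[isSeen], "micro")
  }
  c(pathway = scoreOf(grP), random = scoreOf(grR))
}

#' Prediction-augmented clustering experiment
#'
#' Generates a synthetic dataset, trains the alignment model on its
#' training split, predicts softmax probabilities for every cell, and
#' compares K-Means clustering accuracy (optimal cluster-to-type
#' assignment) on the log-expression features alone versus the features
#' concatenated with the per-cell probabilities. The dataset is smaller
#' than the zero-shot design (fewer, shorter genes and a weaker fold
#' change) so that expression-only clustering is imperfect and the two
#' feature blocks contribute on comparable scales.
#'
#' @param seed integer seed.
#' @param spec synthetic design; the default uses 30 genes, 5 pathways of
#'   5 genes, 6 types (3 adjectives x 2 nouns) with fold change 4, 150
#'   cells per type and no held-out types — a regime where expression-only
#'   K-Means is informative but imperfect and the 6 probability columns
#'   carry weight comparable to the 30 expression columns.
#' @param config model configuration.
#' @param steps training steps.
#' @param restarts random restarts (validation-selected).
#' @param k number of clusters (defaults to the number of types).
#' @return Named numeric vector with elements \code{expression} and
#'   \code{augmented} (clustering accuracy).
#' @export
runAugmentationExperiment <- function(seed = 1L,
                                      spec = NULL,
                                      config = tinyRunConfig(),
                                      steps = 1500L, restarts = 2L,
                                      k = NULL) {
  if (is.null(spec))
    spec <- syntheticSpec(
      nGenes = 30L, nPathways = 5L, genesPerPathway = 5L,
      cellTypes = compositionalCellTypes(c("alpha", "beta", "gamma"),
                                         .DEFAULT_NOUN, foldChange = 4),
      nCellsPerType = 150L, unseenTypes = character(0), seed = seed)
  if (config@batchSize > length(spec@cellTypes))
    config@batchSize <- as.integer(length(spec@cellTypes))
  d <- generateDataset(spec)
  pp <- preprocessCells(d$matrix, minGenes = 0L)
  gr <- buildGrouping(geneIds(pp), d$pathways,
                      orphanSetSize = max(5L, spec@genesPerPathway),
                      seed = spec@seed)
  train <- pp[d$split$train, ]
  model <- trainAlignment(train, gr, config, steps = steps,
                          seed = as.integer(seed) + 101L,
                          validation = pp[d$split$val, ],
                          evalEvery = 250L, restarts = restarts)
  candidates <- vapply(spec@cellTypes, function(ct) ct$name, "")
  pred <- predictCells(model, pp, candidates)
  if (is.null(k)) k <- length(spec@cellTypes)
  truth <- cellNames(pp)
  base <- kmeansCluster(exprValues(pp), k, seed = as.integer(seed) + 11L)
  aug <- kmeansCluster(augmentFeatures(pp, pred@probabilities), k,
                       seed = as.integer(seed) + 11L)
  c(expression = clusteringAccuracy(base, truth),
    augmented = clusteringAccuracy(aug, truth))
}
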