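#' @import methods
NULL

.EXPR_STATES <- c("raw_counts", "normalized_log")

#' ExpressionMatrix: cells-by-genes expression with processing state
#'
#' Container for a cells x genes expression matrix together with gene
#' identifiers, cell barcodes, optional per-cell free-text cell-type names,
#' and a processing-state flag. The state machine is enforced: raw counts
#' must be non-negative integers (within a small round-off tolerance) and
#' normalized/log values must be non-negative. Downstream operations check
#' the state so that, for example, total-count normalization cannot be
#' applied twice.
#'
#' @slot values numeric matrix, cells as rows, genes as columns.
#' @slot cellNames character, per-cell free-text type label; length 0 when
#'   the data are unlabeled.
#' @slot state either \code{"raw_counts"} or \code{"normalized_log"}.
#' @export
setClass("ExpressionMatrix",
  representation(
    values    = "matrix",
    cellNames = "character",
    state     = "character"
  )
)

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry cell ids (rownames) and gene ids (colnames)")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "cell ids must be unique")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "gene ids must be unique")
  }
  if (length(object@cellNames) != 0L && length(object@cellNames) != nrow(v))
    msg <- c(msg, "cellNames must be empty or one per cell")
  if (length(object@state) != 1L || !object@state %in% .EXPR_STATES)
    msg <- c(msg, sprintf("state must be one of: %s",
                          paste(.EXPR_STATES, collapse = ", ")))
  else if (length(v)) {
    if (object@state == "raw_counts" &&
        (any(v < 0) || max(abs(v - round(v))) > 1e-6))
      msg <- c(msg, "state=raw_counts requires non-negative integer values")
    if (object@state == "normalized_log" && any(v < 0))
      msg <- c(msg, "state=normalized_log requires non-negative values")
  }
  if (length(msg)) msg else TRUE
})

#' PathwayCollection: named gene sets
#'
#' A collection of named pathways (gene sets). Pathway ids are unique, every
#' set is non-empty, and a gene may belong to several pathways.
#'
#' @slot sets named list of character vectors of gene identifiers.
#' @export
setClass("PathwayCollection", representation(sets = "list"))

setValidity("PathwayCollection", function(object) {
  s <- object@sets
  msg <- character()
  if (length(s)) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      msg <- c(msg, "every pathway must be named")
    if (anyDuplicated(names(s))) msg <- c(msg, "pathway ids must be unique")
    if (any(vapply(s, length, 1L) == 0L))
      msg <- c(msg, "pathway gene sets must be non-empty")
    if (any(vapply(s, anyDuplicated, 1L) > 0L))
      msg <- c(msg, "genes must not repeat within a pathway")
  }
  if (length(msg)) msg else TRUE
})

#' GeneGrouping: partition-with-overlap of a gene vocabulary into tokens
#'
#' The tokenizer's contract: an ordered list of gene sets (pathway sets
#' followed by seeded random sets for pathway-orphan genes), each stored as
#' indices into the vocabulary. A gene may appear in several pathway groups,
#' but a gene with pathway membership never appears in a random group, and a
#' gene appears in at most one random group.
#'
#' @slot groups list of integer vectors (1-based indices into vocabulary).
#' @slot groupIds character labels, pathway id or \code{"random_k"}.
#' @slot source character, \code{"pathway"} or \code{"random"} per group.
#' @slot vocabulary the gene identifiers the indices refer to.
#' @slot seed integer seed used for shuffling the orphan genes.
#' @slot orphanSetSize integer size of the random groups (last may be short).
#' @export
setClass("GeneGrouping",
  representation(
    groups        = "list",
    groupIds      = "character",
    source        = "character",
    vocabulary    = "character",
    seed          = "integer",
    orphanSetSize = "integer"
  )
)

setValidity("GeneGrouping", function(object) {
  msg <- character()
  g <- object@groups
  n <- length(g)
  if (length(object@groupIds) != n || length(object@source) != n)
    msg <- c(msg, "groups, groupIds and source must have equal length")
  if (!all(object@source %in% c("pathway", "random")))
    msg <- c(msg, "source flags must be 'pathway' or 'random'")
  V <- length(object@vocabulary)
  idx <- unlist(g, use.names = FALSE)
  if (length(idx) && (min(idx) < 1L || max(idx) > V))
    msg <- c(msg, "group indices out of vocabulary range")
  if (length(setdiff(seq_len(V), idx)))
    msg <- c(msg, "every vocabulary gene must appear in at least one group")
  pw <- unique(unlist(g[object@source == "pathway"], use.names = FALSE))
  rnd <- unlist(g[object@source == "random"], use.names = FALSE)
  if (anyDuplicated(rnd))
    msg <- c(msg, "a gene may appear in at most one random group")
  if (length(intersect(pw, rnd)))
    msg <- c(msg, "genes with pathway membership must not appear in random groups")
  rsz <- lengths(g[object@source == "random"])
  if (length(rsz) > 1L && any(rsz[-length(rsz)] != object@orphanSetSize))
    msg <- c(msg, "all random groups but the last must have exactly orphanSetSize genes")
  if (length(msg)) msg else TRUE
})

#' RunConfig: model and pipeline tunables
#'
#' Holds every tunable with its default. The documented production defaults
#' follow the full-scale setting (768-dim gene embeddings, 12 layers,
#' 12 heads, 3072 intermediate features, 512-dim shared space, orphan set
#' size 110, batch size 32, pretraining learning rate 5e-5, contrastive
#' learning rate 1e-5); \code{tinyRunConfig()} gives a desk-scale variant
#' used throughout the examples and tests.
#'
#' @slot embeddingDim gene-embedding dimension D (divisible by nHeads).
#' @slot nLayers,nHeads,intermediateDim transformer encoder geometry.
#' @slot sharedDim dimension of the shared alignment space.
#' @slot textDim native dimension of the built-in text encoder.
#' @slot orphanSetSize size of random gene sets for pathway-orphan genes.
#' @slot batchSize contrastive batch size K (distinct cell names per batch).
#' @slot lrPretrain,lrContrastive Adam learning rates for supervised
#'   pretraining and contrastive alignment.
#' @slot temperature softmax temperature of the contrastive objective.
#' @slot dropout dropout rate inside the transformer during training.
#' @slot maskRate probability that an expression value is zeroed during
#'   training (input-masking augmentation mimicking extra dropout noise);
#'   0 disables.
#' @slot minGenes,minCellFraction,targetSum preprocessing thresholds.
#' @slot seed integer default seed.
#' @export
setClass("RunConfig",
  representation(
    embeddingDim    = "integer",
    nLayers         = "integer",
    nHeads          = "integer",
    intermediateDim = "integer",
    sharedDim       = "integer",
    textDim         = "integer",
    orphanSetSize   = "integer",
    batchSize       = "integer",
    lrPretrain      = "numeric",
    lrContrastive   = "numeric",
    temperature     = "numeric",
    dropout         = "numeric",
    maskRate        = "numeric",
    minGenes        = "integer",
    minCellFraction = "numeric",
    targetSum       = "numeric",
    seed            = "integer"
  ),
  prototype(
    embeddingDim    = 768L,
    nLayers         = 12L,
    nHeads          = 12L,
    intermediateDim = 3072L,
    sharedDim       = 512L,
    textDim         = 128L,
    orphanSetSize   = 110L,
    batchSize       = 32L,
    lrPretrain      = 5e-5,
    lrContrastive   = 1e-5,
    temperature     = 1.0,
    dropout         = 0.1,
    maskRate        = 0.15,
    minGenes        = 200L,
    minCellFraction = 0.001,
    targetSum       = 10000,
    seed            = 1L
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  pos <- c(embeddingDim = object@embeddingDim, nLayers = object@nLayers,
           nHeads = object@nHeads, intermediateDim = object@intermediateDim,
           sharedDim = object@sharedDim, textDim = object@textDim,
           orphanSetSize = object@orphanSetSize, batchSize = object@batchSize)
  if (any(pos < 1L))
    msg <- c(msg, paste("must be positive:",
                        paste(names(pos)[pos < 1L], collapse = ", ")))
  if (object@embeddingDim %% object@nHeads != 0L)
    msg <- c(msg, "embeddingDim must be divisible by nHeads")
  if (object@lrPretrain <= 0 || object@lrContrastive <= 0)
    msg <- c(msg, "learning rates must be positive")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (object@maskRate < 0 || object@maskRate >= 1)
    msg <- c(msg, "maskRate must be in [0, 1)")
  if (object@minGenes < 0 || object@minCellFraction < 0 ||
      object@minCellFraction > 1 || object@targetSum <= 0)
    msg <- c(msg, "invalid preprocessing thresholds")
  if (length(msg)) msg else TRUE
})

#' AlignmentModel: trained encoders and their tokenization
#'
#' The fitted model object: all learnable parameters (gene-embedding table,
#' CLS token, transformer layers, projection heads, built-in text-encoder
#' table, optional classifier head), the configuration, the exact gene
#' grouping used for tokenization, the text-token vocabulary, and the
#' training loss trace.
#'
#' @slot params nested list of numeric parameter arrays.
#' @slot config a \linkS4class{RunConfig}.
#' @slot grouping the \linkS4class{GeneGrouping} this model tokenizes with.
#' @slot textVocab built-in text-encoder token vocabulary (last entry UNK).
#' @slot textKind \code{"builtin"} or \code{"adapter"}.
#' @slot adapter external text encoder callable (names -> matrix), or NULL.
#' @slot classes class labels of the supervised head (may be empty).
#' @slot lossTrace numeric per-step training loss.
#' @slot valScore validation accuracy of the selected checkpoint (length 0
#'   when no validation set was used).
#' @export
setClass("AlignmentModel",
  representation(
    params    = "list",
    config    = "RunConfig",
    grouping  = "GeneGrouping",
    textVocab = "character",
    textKind  = "character",
    adapter   = "ANY",
    classes   = "character",
    lossTrace = "numeric",
    valScore  = "numeric"
  )
)

#' PredictionSet: per-cell zero-shot annotation results
#'
#' One row per cell: cosine similarities against every candidate name,
#' softmax probabilities, the entropy of the seen-candidate-restricted
#' distribution, the maximum-similarity prediction, the out-of-distribution
#' flag, and the final label (the best unseen candidate for flagged cells).
#'
#' @slot cellIds character.
#' @slot candidates candidate names (columns of the score matrices).
#' @slot seenSet subset of candidates seen during training.
#' @slot similarities,probabilities cells x candidates matrices.
#' @slot seenEntropy per-cell entropy (nats) over seen candidates.
#' @slot predictedName global argmax-similarity candidate per cell.
#' @slot oodFlag TRUE where the cell is called an unseen type.
#' @slot finalName predictedName, or best unseen candidate when flagged.
#' @slot threshold the entropy threshold applied (NA before applyOOD).
#' @export
setClass("PredictionSet",
  representation(
    cellIds       = "character",
    candidates    = "character",
    seenSet       = "character",
    similarities  = "matrix",
    probabilities = "matrix",
    seenEntropy   = "numeric",
    predictedName = "character",
    oodFlag       = "logical",
    finalName     = "character",
    threshold     = "numeric"
  )
)

setValidity("PredictionSet", function(object) {
  n <- length(object@cellIds)
  k <- length(object@candidates)
  msg <- character()
  if (anyDuplicated(object@candidates)) msg <- c(msg, "candidates must be unique")
  if (!all(object@seenSet %in% object@candidates))
    msg <- c(msg, "seenSet must be a subset of candidates")
  if (!all(dim(object@similarities) == c(n, k)) ||
      !all(dim(object@probabilities) == c(n, k)))
    msg <- c(msg, "score matrices must be cells x candidates")
  if (n && max(abs(rowSums(object@probabilities) - 1)) > 1e-6)
    msg <- c(msg, "probabilities must sum to 1 per cell")
  if (length(object@seenEntropy) != n || length(object@predictedName) != n ||
      length(object@oodFlag) != n || length(object@finalName) != n)
    msg <- c(msg, "per-cell fields must have one entry per cell")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: design of a generated scRNA-seq dataset
#'
#' Describes a synthetic dataset: the gene universe and its pathway
#' structure, the cell-type roster with pathway-level expression signatures
#' and compositional names, the negative-binomial count model (dispersion,
#' dropout, library-size variation), and the seen/unseen type split used for
#' zero-shot experiments. Unseen-type names are composed only of word tokens
#' that also occur in at least one seen-type name, so name-based zero-shot
#' transfer is exercisable.
#'
#' @slot nGenes,nPathways,genesPerPathway gene-universe geometry.
#' @slot pathwayOverlapFraction fraction of genes shared between consecutive
#'   pathways.
#' @slot cellTypes list of lists with fields \code{name},
#'   \code{signaturePathways} (indices), \code{foldChange}.
#' @slot nCellsPerType cells generated per type.
#' @slot baseMean baseline negative-binomial mean per gene.
#' @slot dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @slot dropoutRate probability an observed count is zeroed.
#' @slot librarySizeCV coefficient of variation of per-cell library factors.
#' @slot unseenTypes names held out of training.
#' @slot seed integer seed; the dataset is fully determined by it.
#' @export
setClass("SyntheticSpec",
  representation(
    nGenes                 = "integer",
    nPathways              = "integer",
    genesPerPathway        = "integer",
    pathwayOverlapFraction = "numeric",
    cellTypes              = "list",
    nCellsPerType          = "integer",
    baseMean               = "numeric",
    dispersion             = "numeric",
    dropoutRate            = "numeric",
    librarySizeCV          = "numeric",
    unseenTypes            = "character",
    seed                   = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nGenes < 1L || object@nPathways < 0L || object@genesPerPathway < 1L)
    msg <- c(msg, "gene-universe sizes must be positive")
  if (object@pathwayOverlapFraction < 0 || object@pathwayOverlapFraction >= 1)
    msg <- c(msg, "pathwayOverlapFraction must be in [0, 1)")
  names_ <- vapply(object@cellTypes, function(ct) ct$name, "")
  if (anyDuplicated(names_)) msg <- c(msg, "cell-type names must be unique")
  fc <- vapply(object@cellTypes, function(ct) ct$foldChange, 1.0)
  if (any(fc < 1)) msg <- c(msg, "foldChange must be >= 1")
  if (!all(object@unseenTypes %in% names_))
    msg <- c(msg, "unseenTypes must name declared cell types")
  seen <- setdiff(names_, object@unseenTypes)
  seenTok <- unique(unlist(lapply(seen, .tokenizeName)))
  for (u in object@unseenTypes) {
    extra <- setdiff(.tokenizeName(u), seenTok)
    if (length(extra))
      msg <- c(msg, sprintf(
        "unseen type '%s' uses tokens absent from all seen names: %s",
        u, paste(extra, collapse = ", ")))
  }
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must be in [0, 1]")
  if (object@dispersion < 0 || object@librarySizeCV < 0 || object@baseMean <= 0)
    msg <- c(msg, "count-model parameters out of range")
  if (length(msg)) msg else TRUE
})
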