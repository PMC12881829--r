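#' Build the pathway-informed gene grouping
#'
#' Partitions (with overlap) a gene vocabulary into the "super tokens" fed
#' to the expression transformer. Each pathway, intersected with the
#' vocabulary, becomes one group (empty intersections are dropped); a gene
#' belonging to several pathways appears in each of them. The remaining
#' "orphan" genes — those in no pathway — are shuffled by \code{seed} and
#' chunked into consecutive random groups of \code{orphanSetSize} genes;
#' the last random group may be smaller when the orphan count is not a
#' multiple of the set size, so the number of random groups is
#' \code{ceiling(nOrphan / orphanSetSize)}.
#'
#' The construction is deterministic given the vocabulary order, the
#' pathway collection, the set size and the seed; changing the seed permutes
#' only random-group membership, never the pathway groups.
#'
#' @param vocabulary character vector of gene ids (the model's gene order).
#' @param pathwayCollection a \linkS4class{PathwayCollection}; genes listed
#'   in a pathway but absent from the vocabulary are dropped from that
#'   group.
#' @param orphanSetSize size of the random orphan groups (default 110).
#' @param seed integer seed for the orphan shuffle.
#' @return A \linkS4class{GeneGrouping}.
#' @examples
#' pw <- PathwayCollection(list(P1 = c("g1", "g2"), P2 = c("g2", "g3")))
#' gr <- buildGrouping(paste0("g", 1:6), pw, orphanSetSize = 2, seed = 1)
#' tokensPerProfile(gr)
#' @export
buildGrouping <- function(vocabulary, pathwayCollection,
                          orphanSetSize = 110L, seed = 1L) {
  vocabulary <- as.character(vocabulary)
  if (!length(vocabulary)) stop("vocabulary must be non-empty")
  if (anyDuplicated(vocabulary)) stop("vocabulary genes must be unique")
  orphanSetSize <- as.integer(orphanSetSize)
  if (is.na(orphanSetSize) || orphanSetSize < 1L)
    stop("orphanSetSize must be >= 1")
  stopifnot(is(pathwayCollection, "PathwayCollection"))

  lookup <- seq_along(vocabulary)
  names(lookup) <- vocabulary
  pwGroups <- lapply(pathways(pathwayCollection), function(g) {
    unname(lookup[g[g %in% vocabulary]])
  })
  keep <- lengths(pwGroups) > 0L
  pwGroups <- pwGroups[keep]
  pwIds <- names(pathways(pathwayCollection))[keep]

  inPathway <- logical(length(vocabulary))
  inPathway[unlist(pwGroups, use.names = FALSE)] <- TRUE
  orphan <- which(!inPathway)
  rndGroups <- list()
  if (length(orphan)) {
    orphan <- .withSeed(as.integer(seed),
                        orphan[sample.int(length(orphan))])
    nRnd <- ceiling(length(orphan) / orphanSetSize)
    rndGroups <- split(orphan, rep(seq_len(nRnd),
                                   each = orphanSetSize)[seq_along(orphan)])
    rndGroups <- lapply(unname(rndGroups), as.integer)
  }
  new("GeneGrouping",
      groups        = unname(c(lapply(pwGroups, as.integer), rndGroups)),
      groupIds      = c(pwIds, sprintf("random_%d", seq_along(rndGroups))),
      source        = c(rep("pathway", length(pwGroups)),
                        rep("random", length(rndGroups))),
      vocabulary    = vocabulary,
      seed          = as.integer(seed),
      orphanSetSize = orphanSetSize)
}

#' @describeIn GeneGrouping-class number of gene-set tokens M per profile
#'   (the CLS token is added by the encoder, not counted here).
#' @export
setMethod("tokensPerProfile", "GeneGrouping", function(x) length(x@groups))

#' @rdname GeneGrouping-class
#' @export
setMethod("groupIds", "GeneGrouping", function(x) x@groupIds)

#' @rdname GeneGrouping-class
#' @export
setMethod("groupSource", "GeneGrouping", function(x) x@source)

#' @describeIn GeneGrouping-class groups as lists of gene identifiers.
#' @export
setMethod("groupGenes", "GeneGrouping", function(x) {
  out <- lapply(x@groups, function(i) x@vocabulary[i])
  names(out) <- x@groupIds
  out
})

setMethod("show", "GeneGrouping", function(object) {
  nP <- sum(object@source == "pathway")
  nR <- sum(object@source == "random")
  cat(sprintf(
    "GeneGrouping: %d tokens (%d pathway + %d random), %d genes, seed %d\n",
    length(object@groups), nP, nR, length(object@vocabulary), object@seed))
})

#' Serialize a GeneGrouping to JSON
#'
#' Writes group ids, sources, member gene ids, the vocabulary, the seed and
#' the orphan set size, so a trained model ships with its exact
#' tokenization.
#'
#' @param grouping a \linkS4class{GeneGrouping}.
#' @param path output .json path.
#' @export
writeGrouping <- function(grouping, path) {
  stopifnot(is(grouping, "GeneGrouping"))
  obj <- list(
    vocabulary     = grouping@vocabulary,
    group_ids      = grouping@groupIds,
    source         = grouping@source,
    groups         = lapply(grouping@groups, function(i) grouping@vocabulary[i]),
    seed           = grouping@seed,
    orphan_set_size = grouping@orphanSetSize)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeneGrouping from JSON
#'
#' @param path a file written by \code{\link{writeGrouping}}.
#' @return The reconstructed \linkS4class{GeneGrouping}.
#' @export
readGrouping <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- as.character(obj$vocabulary)
  lookup <- seq_along(vocab)
  names(lookup) <- vocab
  groups <- obj$groups
  if (is.data.frame(groups)) groups <- as.list(groups)
  new("GeneGrouping",
      groups        = unname(lapply(groups, function(g) as.integer(unname(lookup[as.character(g)])))),
      groupIds      = as.character(obj$group_ids),
      source        = as.character(obj$source),
      vocabulary    = vocab,
      seed          = as.integer(obj$seed),
      orphanSetSize = as.integer(obj$orphan_set_size))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
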