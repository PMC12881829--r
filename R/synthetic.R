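#' Compositional cell-type roster
#'
#' Builds a cell-type roster whose names are composed from a grid of
#' adjective and noun tokens ("alpha helper cell", "beta killer cell",
#' ...), with each distinct token tied to its own signature pathway:
#' adjective i maps to pathway i and noun j to pathway
#' \code{length(adjectives) + j}, so a type's expression signature is the
#' union of its two token pathways. Because signatures compose exactly as
#' names do, a model that aligns name tokens with pathway activity can
#' generalize to held-out name combinations — the desk-scale stand-in for
#' the semantic generalization a pretrained language model provides on
#' real cell names.
#'
#' @param adjectives,nouns character token vectors.
#' @param foldChange expression fold change of signature-pathway genes.
#' @return A list of cell-type descriptors (\code{name},
#'   \code{signaturePathways}, \code{foldChange}).
#' @export
compositionalCellTypes <- function(adjectives, nouns, foldChange = 4) {
  out <- list()
  for (j in seq_along(nouns))
    for (i in seq_along(adjectives))
      out[[length(out) + 1L]] <- list(
        name = paste(adjectives[i], nouns[j], "cell"),
        signaturePathways = c(i, length(adjectives) + j),
        foldChange = foldChange)
  out
}

.DEFAULT_ADJ <- c("alpha", "beta", "gamma", "delta", "epsilon")
.DEFAULT_NOUN <- c("helper", "killer")

#' Specify a synthetic scRNA-seq dataset
#'
#' Returns a \linkS4class{SyntheticSpec} with the default desk-scale
#' design: 600 genes, 20 disjoint pathways of 15 genes (half the genes
#' remain pathway-orphan), a 10-type compositional roster (5 adjectives x
#' 2 nouns) with fold change 4 on token-linked signature pathways, 150
#' cells per type, negative-binomial counts (base mean 2, dispersion
#' 0.25), dropout 0.2, 20% library-size CV, and 2 unseen types
#' ("gamma helper cell", "delta killer cell") whose name tokens all occur
#' in seen names.
#'
#' @param ... slot overrides (see \linkS4class{SyntheticSpec}).
#' @return A validated \linkS4class{SyntheticSpec}.
#' @examples
#' sp <- syntheticSpec(nCellsPerType = 50, seed = 3)
#' @export
syntheticSpec <- function(...) {
  defaults <- list(
    nGenes = 600L, nPathways = 20L, genesPerPathway = 15L,
    pathwayOverlapFraction = 0,
    cellTypes = compositionalCellTypes(.DEFAULT_ADJ, .DEFAULT_NOUN),
    nCellsPerType = 150L, baseMean = 2, dispersion = 0.25,
    dropoutRate = 0.2, librarySizeCV = 0.2,
    unseenTypes = c("gamma helper cell", "delta killer cell"),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown SyntheticSpec fields: ",
                        paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  intS <- c("nGenes", "nPathways", "genesPerPathway", "nCellsPerType", "seed")
  for (s in intS) defaults[[s]] <- as.integer(defaults[[s]])
  do.call(new, c(list("SyntheticSpec"), defaults))
}

.geneUniverse <- function(spec)
  sprintf("g%04d", seq_len(spec@nGenes))

#' Generate the pathway structure of a synthetic dataset
#'
#' Draws pathways from the shuffled gene universe. Consecutive pathways
#' share \code{floor(overlap * genesPerPathway)} genes; genes not placed
#' in any pathway remain orphan (and will be tokenized into random
#' groups). Deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return A \linkS4class{PathwayCollection}.
#' @export
generatePathways <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  gpp <- spec@genesPerPathway
  nShared <- as.integer(floor(spec@pathwayOverlapFraction * gpp))
  needed <- gpp + (spec@nPathways - 1L) * (gpp - nShared)
  if (spec@nPathways > 0L && needed > spec@nGenes)
    stop("infeasible pathway sizes: need ", needed, " genes, have ",
         spec@nGenes)
  genes <- .geneUniverse(spec)
  pool <- .withSeed(spec@seed, sample(genes))
  sets <- list()
  cursor <- 0L
  prev <- character(0)
  for (i in seq_len(spec@nPathways)) {
    fresh <- if (i == 1L) gpp else gpp - nShared
    take <- pool[cursor + seq_len(fresh)]
    cursor <- cursor + fresh
    shared <- if (i == 1L) character(0) else utils::tail(prev, nShared)
    prev <- c(shared, take)
    sets[[sprintf("PW%02d", i)]] <- prev
  }
  PathwayCollection(sets)
}

#' Generate synthetic cells
#'
#' Simulates counts for every cell type in the spec: a gene's mean is
#' \code{baseMean * foldChange} when the gene lies in any signature
#' pathway of the type and \code{baseMean} otherwise; counts are
#' negative-binomial with the stated dispersion (Poisson when dispersion
#' is 0), scaled by a per-cell log-normal library-size factor (unit mean,
#' CV \code{librarySizeCV}), and zeroed independently with probability
#' \code{dropoutRate}. Fully determined by the spec's seed.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param pathways the matching \code{\link{generatePathways}} output.
#' @return An \linkS4class{ExpressionMatrix} in \code{raw_counts} state
#'   with per-cell type names.
#' @export
generateCells <- function(spec, pathways) {
  stopifnot(is(spec, "SyntheticSpec"), is(pathways, "PathwayCollection"))
  genes <- .geneUniverse(spec)
  sets <- pathways(pathways)
  maxIdx <- max(c(0L, unlist(lapply(spec@cellTypes,
                                    function(ct) ct$signaturePathways))))
  if (maxIdx > length(sets))
    stop("signaturePathways index ", maxIdx, " exceeds the ",
         length(sets), " generated pathways")
  nG <- spec@nGenes
  nPer <- spec@nCellsPerType
  nTypes <- length(spec@cellTypes)
  sdlog <- sqrt(log(1 + spec@librarySizeCV^2))

  .withSeed(spec@seed + 1L, {
    values <- matrix(0, nTypes * nPer, nG)
    nms <- character(nTypes * nPer)
    row <- 0L
    for (ct in spec@cellTypes) {
      sig <- unique(unlist(sets[ct$signaturePathways]))
      mu <- rep(spec@baseMean, nG)
      mu[match(sig, genes)] <- spec@baseMean * ct$foldChange
      for (i in seq_len(nPer)) {
        row <- row + 1L
        lib <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        cnt <- if (spec@dispersion > 0)
          stats::rnbinom(nG, mu = mu * lib, size = 1 / spec@dispersion)
        else stats::rpois(nG, mu * lib)
        if (spec@dropoutRate > 0)
          cnt[stats::runif(nG) < spec@dropoutRate] <- 0L
        values[row, ] <- cnt
        nms[row] <- ct$name
      }
    }
    dimnames(values) <- list(sprintf("cell_%05d", seq_len(nrow(values))),
                             genes)
    ExpressionMatrix(values, cellNames = nms, state = "raw_counts")
  })
}

#' Train/validation/test split with held-out unseen types
#'
#' All cells of unseen types go to the test set. Cells of each seen type
#' are shuffled and split by the configured ratio (default 7:1:2
#' train:validation:test), with per-type counts within one cell of the
#' exact ratio. A seen type with fewer than 3 cells goes entirely to the
#' training set with a warning.
#'
#' @param m a labeled \linkS4class{ExpressionMatrix}.
#' @param unseenTypes type names held out of training entirely.
#' @param ratio length-3 positive weights for train/val/test.
#' @param seed integer seed for the per-type shuffles.
#' @return A manifest list: integer index vectors \code{train},
#'   \code{val}, \code{test}, and name vectors \code{seen},
#'   \code{unseen}.
#' @export
makeSplit <- function(m, unseenTypes = character(0),
                      ratio = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(is(m, "ExpressionMatrix"))
  nms <- cellNames(m)
  if (!length(nms)) stop("makeSplit requires labeled cells")
  if (length(ratio) != 3L || any(ratio < 0) || sum(ratio) <= 0)
    stop("ratio must be 3 non-negative weights")
  ratio <- ratio / sum(ratio)
  unseenTypes <- .normalizeNames(unseenTypes)
  types <- unique(nms)
  missing <- setdiff(unseenTypes, types)
  if (length(missing))
    stop("unseen types absent from the data: ",
         paste(missing, collapse = ", "))
  seen <- setdiff(types, unseenTypes)
  train <- val <- test <- integer(0)
  .withSeed(as.integer(seed), {
    for (ty in seen) {
      idx <- which(nms == ty)
      if (length(idx) < 3L) {
        warning("seen type '", ty, "' has fewer than 3 cells; ",
                "assigning all of them to the training set")
        train <- c(train, idx)
        next
      }
      idx <- sample(idx)
      bounds <- round(cumsum(ratio) * length(idx))
      sizes <- diff(c(0L, bounds))
      parts <- split(idx, rep(1:3, sizes))
      train <- c(train, parts[["1"]])
      val <- c(val, parts[["2"]])
      test <- c(test, parts[["3"]])
    }
  })
  test <- c(test, which(nms %in% unseenTypes))
  list(train = sort(train), val = sort(val), test = sort(test),
       seen = seen, unseen = unseenTypes)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: generates the pathway structure, the cells and
#' the split manifest for a spec.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param ratio split ratio passed to \code{\link{makeSplit}}.
#' @return A list with \code{pathways}, \code{matrix} and \code{split}.
#' @export
generateDataset <- function(spec, ratio = c(0.7, 0.1, 0.2)) {
  pw <- generatePathways(spec)
  m <- generateCells(spec, pw)
  list(pathways = pw, matrix = m,
       split = makeSplit(m, spec@unseenTypes, ratio, seed = spec@seed + 2L))
}
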