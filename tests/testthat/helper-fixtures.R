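# Shared fixtures, built in code. The cache environment persists for the
# whole test session so expensive objects are constructed once.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# a tiny handmade count matrix: 4 cells x 5 genes
tinyCounts <- function() {
  m <- matrix(c(0, 1, 2, 0, 5,
                3, 0, 0, 1, 2,
                1, 1, 1, 1, 1,
                0, 0, 4, 0, 0), 4, 5, byrow = TRUE,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:5)))
  ExpressionMatrix(m, cellNames = c("a x", "a y", "b x", "b y"),
                   state = "raw_counts")
}

# small labeled dataset with clear pathway-linked signatures, plus its
# grouping -- cheap enough for training smoke tests
smallTrainingSet <- function() {
  cached("smallTrainingSet", {
    spec <- syntheticSpec(
      nGenes = 40L, nPathways = 5L, genesPerPathway = 6L,
      cellTypes = compositionalCellTypes(c("alpha", "beta", "gamma"),
                                         c("helper", "killer"),
                                         foldChange = 6),
      nCellsPerType = 30L, unseenTypes = character(0), seed = 42L)
    d <- generateDataset(spec)
    pp <- preprocessCells(d$matrix, minGenes = 0L)
    gr <- buildGrouping(geneIds(pp), d$pathways, orphanSetSize = 5L,
                        seed = 1L)
    list(spec = spec, data = d, pp = pp, grouping = gr)
  })
}

# an untrained desk-scale model over a random vocabulary, for geometry and
# determinism tests that do not need training
untrainedModel <- function(D = 16L, nGroups = 10L, seed = 3L) {
  vocab <- sprintf("v%03d", seq_len(nGroups * 4L))
  sets <- split(vocab, rep(seq_len(nGroups), each = 4L))
  names(sets) <- sprintf("S%02d", seq_len(nGroups))
  gr <- buildGrouping(vocab, PathwayCollection(sets), orphanSetSize = 4L,
                      seed = seed)
  cfg <- tinyRunConfig(embeddingDim = D, nHeads = 4L,
                       intermediateDim = 2L * D, sharedDim = D,
                       textDim = 8L)
  model <- initModel(gr, c("a x", "b y", "c z"), cfg, seed = seed)
  list(model = model, grouping = gr, config = cfg, vocab = vocab)
}

randomProfileMatrix <- function(n, vocab, seed = 1L) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n * length(vocab))), n, length(vocab),
              dimnames = list(sprintf("cell%02d", seq_len(n)), vocab))
  ExpressionMatrix(m, state = "normalized_log")
}
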