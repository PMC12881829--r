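test_that("pathway generation honours overlap, orphan fraction and seed", {
  spec <- syntheticSpec(nGenes = 1000L, nPathways = 10L,
                        genesPerPathway = 50L, pathwayOverlapFraction = 0,
                        seed = 3L)
  pw <- generatePathways(spec)
  genes <- unlist(pathways(pw))
  expect_equal(anyDuplicated(genes), 0L)          # overlap 0 -> disjoint
  expect_equal(length(unique(genes)), 500L)       # 500 of 1000 orphan
  expect_identical(pathways(generatePathways(spec)), pathways(pw))
  specO <- syntheticSpec(nGenes = 100L, nPathways = 4L,
                         genesPerPathway = 20L,
                         pathwayOverlapFraction = 0.5, seed = 3L)
  pwO <- pathways(generatePathways(specO))
  for (i in 2:4)
    expect_length(intersect(pwO[[i - 1]], pwO[[i]]), 10L)
  expect_error(generatePathways(
    syntheticSpec(nGenes = 50L, nPathways = 10L, genesPerPathway = 20L)),
    "infeasible")
})

test_that("degenerate dropout produces an all-zero matrix", {
  spec <- syntheticSpec(nGenes = 30L, nPathways = 2L, genesPerPathway = 5L,
                        cellTypes = list(list(name = "solo cell",
                                              signaturePathways = 1L,
                                              foldChange = 2)),
                        nCellsPerType = 5L, dropoutRate = 1,
                        unseenTypes = character(0), seed = 1L)
  m <- generateCells(spec, generatePathways(spec))
  expect_true(all(exprValues(m) == 0))
  expect_equal(exprState(m), "raw_counts")
})

test_that("signature genes recover the specified fold change", {
  spec <- syntheticSpec(nGenes = 200L, nPathways = 4L,
                        genesPerPathway = 20L,
                        cellTypes = list(list(name = "solo cell",
                                              signaturePathways = c(1L, 2L),
                                              foldChange = 4)),
                        nCellsPerType = 300L, dropoutRate = 0.2,
                        unseenTypes = character(0), seed = 8L)
  pw <- generatePathways(spec)
  m <- generateCells(spec, pw)
  sig <- unique(unlist(pathways(pw)[1:2]))
  bg <- setdiff(geneIds(m), unique(unlist(pathways(pw))))
  ratio <- mean(exprValues(m)[, sig]) / mean(exprValues(m)[, bg])
  expect_lt(abs(ratio - 4) / 4, 0.05)
})

test_that("the generator is byte-identical under a fixed seed", {
  spec <- syntheticSpec(nCellsPerType = 10L, seed = 17L)
  d1 <- generateDataset(spec)
  d2 <- generateDataset(spec)
  expect_identical(exprValues(d1$matrix), exprValues(d2$matrix))
  expect_identical(d1$split, d2$split)
})

test_that("a null-signal dataset trains to chance-level accuracy", {
  spec <- syntheticSpec(
    nGenes = 40L, nPathways = 5L, genesPerPathway = 6L,
    cellTypes = compositionalCellTypes(c("alpha", "beta"),
                                       c("helper", "killer"),
                                       foldChange = 1 + 1e-9),
    nCellsPerType = 40L, unseenTypes = character(0), seed = 5L)
  d <- generateDataset(spec)
  pp <- preprocessCells(d$matrix, minGenes = 0L)
  gr <- buildGrouping(geneIds(pp), d$pathways, orphanSetSize = 5L,
                      seed = 1L)
  model <- trainClassifier(pp[d$split$train, ], gr,
                           tinyRunConfig(batchSize = 16L),
                           steps = 150L, seed = 2L)
  test <- pp[d$split$test, ]
  acc <- mean(classifyCells(model, test)$labels == cellNames(test))
  n <- nrow(exprValues(test))
  # binomial CI around chance = 1/4
  expect_lt(abs(acc - 0.25), 4 * sqrt(0.25 * 0.75 / n))
})

test_that("splitting holds out unseen types and keeps stratified ratios", {
  spec <- syntheticSpec(nCellsPerType = 50L, seed = 2L)
  d <- generateDataset(spec)
  m <- d$matrix
  split <- makeSplit(m, spec@unseenTypes, seed = 4L)
  nms <- cellNames(m)
  expect_setequal(split$unseen, spec@unseenTypes)
  expect_length(split$seen, 8L)
  # every unseen-type cell is in test
  unseenIdx <- which(nms %in% spec@unseenTypes)
  expect_true(all(unseenIdx %in% split$test))
  expect_length(intersect(unseenIdx, c(split$train, split$val)), 0L)
  # per seen type the 7:1:2 ratio holds within one cell
  for (ty in split$seen) {
    idx <- which(nms == ty)
    expect_lte(abs(sum(idx %in% split$train) - 35), 1)
    expect_lte(abs(sum(idx %in% split$val) - 5), 1)
    expect_lte(abs(sum(idx %in% split$test) - 10), 1)
  }
  # no unseen types: a plain ratio split covering all cells
  splitAll <- makeSplit(m, character(0), seed = 4L)
  expect_length(c(splitAll$train, splitAll$val, splitAll$test), length(nms))
})

test_that("tiny seen types fall back to training with a warning", {
  v <- matrix(1:12, 4, 3,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  m <- ExpressionMatrix(v, cellNames = c("rare q", "rare q", "common w",
                                         "common w"),
                        state = "normalized_log")
  warns <- character(0)
  withCallingHandlers(
    split <- makeSplit(m, character(0), seed = 1L),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_length(warns, 2L)                 # both tiny types warned
  expect_match(warns, "fewer than 3", all = TRUE)
  expect_true(all(which(cellNames(m) == "rare q") %in% split$train))
})

test_that("unseen names must recombine tokens present in seen names", {
  expect_error(syntheticSpec(
    cellTypes = list(list(name = "alpha helper cell",
                          signaturePathways = 1L, foldChange = 2),
                     list(name = "omega helper cell",
                          signaturePathways = 2L, foldChange = 2)),
    unseenTypes = "omega helper cell"),
    "tokens absent")
})
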