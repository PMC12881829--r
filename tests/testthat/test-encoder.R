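test_that("gene-set embedding is the expression-weighted average", {
  tab <- rbind(c(1, 1), c(5, 5), c(2, -2))
  # zero expression -> zero vector
  expect_equal(embedGeneSet(c(0, 0, 0), 1:3, tab), c(0, 0))
  # single gene with x = 1 -> that gene's row
  expect_equal(embedGeneSet(c(0, 1, 0), 2L, tab), c(5, 5))
  # hand case: (2*(1,1) + 0*(5,5)) / 2, zero-expression gene in denominator
  expect_equal(embedGeneSet(c(2, 0, 0), 1:2, tab), c(1, 1))
  expect_error(embedGeneSet(c(1, 2), integer(0), tab), "non-empty")
})

test_that("gene-set embedding is positively homogeneous in the profile", {
  set.seed(1)
  tab <- matrix(rnorm(40), 10, 4)
  x <- abs(rnorm(10))
  g <- c(2L, 5L, 9L)
  for (alpha in c(0, 0.5, 3)) {
    expect_equal(embedGeneSet(alpha * x, g, tab),
                 alpha * embedGeneSet(x, g, tab))
  }
})

test_that("token sequences prepend a shared CLS row and follow group order", {
  um <- untrainedModel()
  tab <- um$model@params$gene
  cls <- um$model@params$cls
  x1 <- stats::setNames(abs(rnorm(length(um$vocab))), um$vocab)
  x2 <- stats::setNames(abs(rnorm(length(um$vocab))), um$vocab)
  t1 <- buildTokenSequence(x1, um$grouping, tab, cls)
  t2 <- buildTokenSequence(x2, um$grouping, tab, cls)
  expect_equal(nrow(t1), tokensPerProfile(um$grouping) + 1L)
  expect_equal(t1[1, ], t2[1, ])                  # identical CLS before encoding
  expect_error(buildTokenSequence(x1[-1], um$grouping, tab, cls),
               "missing grouping genes")
})

test_that("the encoder is deterministic in eval mode with D-dim output", {
  um <- untrainedModel()
  m <- randomProfileMatrix(5, um$vocab, seed = 2L)
  e1 <- encodeCells(um$model, m)
  e2 <- encodeCells(um$model, m)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(5L, um$config@embeddingDim))
  expect_true(all(is.finite(e1)))
})

test_that("CLS output is invariant to permuting gene-set tokens", {
  um <- untrainedModel()                          # 2 layers
  m <- randomProfileMatrix(3, um$vocab, seed = 4L)
  base <- encodeCells(um$model, m)
  set.seed(11)
  for (rep in 1:5) {
    perm <- sample(length(um$grouping@groups))
    permModel <- um$model
    permModel@grouping@groups <- um$grouping@groups[perm]
    permModel@grouping@groupIds <- um$grouping@groupIds[perm]
    permModel@grouping@source <- um$grouping@source[perm]
    permuted <- encodeCells(permModel, m)
    expect_lt(max(abs(permuted - base)), 1e-5)
  }
})

test_that("a supervised head fits a tiny separable task to accuracy 1", {
  sm <- smallTrainingSet()
  keep <- cellNames(sm$pp) %in% c("alpha helper cell", "beta killer cell",
                                  "gamma helper cell")
  subset <- sm$pp[keep, ]
  cfg <- tinyRunConfig(batchSize = 16L)
  model <- trainClassifier(subset, sm$grouping, cfg, steps = 250L, seed = 7L)
  out <- classifyCells(model, subset)
  expect_equal(ncol(out$logits), 3L)
  expect_equal(unname(rowSums(out$probabilities)), rep(1, nrow(out$logits)),
               tolerance = 1e-8)
  expect_equal(mean(out$labels == cellNames(subset)), 1.0)
})

test_that("one training step sends nonzero gradients to every component", {
  ns <- asNamespace("scPathAlign")
  um <- untrainedModel()
  cfg <- um$config
  m <- randomProfileMatrix(3, um$vocab, seed = 6L)
  X <- exprValues(m)
  params <- um$model@params
  params$head <- list(W = matrix(rnorm(cfg@embeddingDim * 2, sd = 0.2),
                                 cfg@embeddingDim, 2), b = c(0, 0))
  enc <- ns$.encForward(params, X, um$grouping@groups, cfg)
  logits <- ns$.addB(enc$cls %*% params$head$W, params$head$b)
  P <- ns$.softmaxRows(logits)
  y <- c(1L, 2L, 1L)
  dLogits <- P
  dLogits[cbind(1:3, y)] <- dLogits[cbind(1:3, y)] - 1
  encG <- ns$.encBackward(params, enc$cache, dLogits %*% t(params$head$W))
  expect_gt(max(abs(encG$gene)), 0)
  expect_gt(max(abs(encG$cls)), 0)
  for (l in seq_along(encG$layers))
    for (leaf in encG$layers[[l]])
      expect_gt(max(abs(leaf)), 0)
  expect_gt(max(abs(t(enc$cls) %*% dLogits)), 0)  # head gradient
})

test_that("model checkpoints round-trip through a directory", {
  sm <- smallTrainingSet()
  cfg <- tinyRunConfig(batchSize = 6L)
  model <- trainAlignment(sm$pp, sm$grouping, cfg, steps = 5L, seed = 1L)
  dir <- withr::local_tempdir()
  saveModel(model, dir)
  back <- loadModel(dir)
  expect_equal(back@params, model@params)
  expect_identical(back@textVocab, model@textVocab)
  expect_equal(back@lossTrace, model@lossTrace)
  m <- sm$pp[1:4, ]
  expect_equal(encodeCells(back, m), encodeCells(model, m))
})
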