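test_that("seen entropy has its closed-form values", {
  expect_equal(seenEntropy(rep(0.25, 4), rep(TRUE, 4)), log(4))
  expect_equal(seenEntropy(c(1, 0, 0), rep(TRUE, 3)), 0)
  expect_equal(seenEntropy(c(0.5, 0.25, 0.25), rep(TRUE, 3)), 1.0397,
               tolerance = 1e-4)
  # renormalization over the seen subset
  expect_equal(seenEntropy(c(0.2, 0.2, 0.6), c(TRUE, TRUE, FALSE)), log(2))
  expect_error(seenEntropy(c(0, 0, 1), c(TRUE, TRUE, FALSE)), "zero")
})

test_that("seen entropy matches -sum p log p on random distributions", {
  set.seed(5)
  for (trial in 1:100) {
    n <- sample(2:8, 1)
    p <- runif(n)
    p <- p / sum(p)
    expect_equal(seenEntropy(p, rep(TRUE, n)), -sum(p * log(p)),
                 tolerance = 1e-9)
  }
})

test_that("the OOD threshold is the interpolated median", {
  expect_equal(oodThreshold(c(1, 2, 3)), 2)
  expect_equal(oodThreshold(c(1, 3)), 2)
  set.seed(9)
  x <- rgamma(1000, 2)
  s <- sort(x)
  expect_equal(oodThreshold(x), (s[500] + s[501]) / 2, tolerance = 1e-9)
  expect_error(oodThreshold(numeric(0)), "non-empty")
})

makePred <- function(entropy, sims, candidates, seen) {
  n <- length(entropy)
  probs <- matrix(1 / length(candidates), n, length(candidates))
  new("PredictionSet", cellIds = sprintf("c%d", seq_len(n)),
      candidates = candidates, seenSet = seen,
      similarities = sims, probabilities = probs,
      seenEntropy = entropy,
      predictedName = candidates[max.col(sims, ties.method = "first")],
      oodFlag = rep(FALSE, n),
      finalName = candidates[max.col(sims, ties.method = "first")],
      threshold = NA_real_)
}

test_that("OOD flagging is strict and reassigns to the best unseen name", {
  sims <- rbind(c(0.9, 0.1, 0.3), c(0.8, 0.2, 0.4), c(0.1, 0.2, 0.9))
  p <- makePred(c(0.2, 0.5, 0.8), sims, c("s1", "s2", "u1"), c("s1", "s2"))
  out <- applyOOD(p, 0.5)
  expect_identical(out@oodFlag, c(FALSE, FALSE, TRUE))   # 0.5 not flagged
  expect_identical(out@finalName[3], "u1")
  expect_identical(applyOOD(p, Inf)@finalName, p@predictedName)
  allFlagged <- applyOOD(p, -Inf)
  expect_true(all(allFlagged@oodFlag))
  expect_true(all(allFlagged@finalName == "u1"))
  pNoUnseen <- makePred(c(0.2, 0.8), sims[1:2, 1:2], c("s1", "s2"),
                        c("s1", "s2"))
  expect_error(applyOOD(pNoUnseen, 0.5), "no unseen candidates")
})

test_that("the median threshold flags half the cells up to 1/n", {
  set.seed(21)
  for (n in c(10, 11, 101, 500)) {
    ent <- runif(n)
    sims <- matrix(runif(n * 3), n, 3)
    p <- makePred(ent, sims, c("s1", "s2", "u1"), c("s1", "s2"))
    out <- applyOOD(p, oodThreshold(ent))
    expect_lte(abs(mean(out@oodFlag) - 0.5), 1 / n + 1e-12)
  }
})

test_that("prediction over candidates is argmax cosine with contract checks", {
  um <- untrainedModel()
  m <- randomProfileMatrix(6, um$vocab, seed = 12L)
  # one candidate: always predicted; entropy 0 when it is seen
  p1 <- predictCells(um$model, m, "a x")
  expect_true(all(p1@predictedName == "a x"))
  expect_equal(unname(p1@seenEntropy), rep(0, 6))
  expect_error(predictCells(um$model, m, c("a x", "a x")), "unique")
  expect_error(predictCells(um$model, m, c("a x"), seenSet = "b y"),
               "subset")
  # candidate order does not change the winner
  cands <- c("a x", "b y", "c z")
  pA <- predictCells(um$model, m, cands)
  pB <- predictCells(um$model, m, rev(cands))
  expect_identical(pA@predictedName, pB@predictedName)
  expect_equal(unname(rowSums(pA@probabilities)), rep(1, 6),
               tolerance = 1e-9)
  # name embeddings are shared across cells: similarities consistent
  expect_equal(pA@similarities[, "b y"], pB@similarities[, "b y"])
})

test_that("annotateCells applies the median threshold end to end", {
  um <- untrainedModel()
  m <- randomProfileMatrix(8, um$vocab, seed = 13L)
  out <- annotateCells(um$model, m, c("a x", "b y", "c z"),
                       seenSet = c("a x", "b y"))
  expect_false(is.na(out@threshold))
  expect_lte(abs(mean(out@oodFlag) - 0.5), 1 / 8)
  df <- predictions(out)
  expect_identical(names(df),
                   c("cell_id", "predicted_name", "top_similarity",
                     "seen_entropy", "ood_flag", "final_name"))
})
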