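test_that("cosine similarity matches hand computations", {
  # orthonormal matching rows -> identity
  C <- diag(3)
  expect_equal(similarityMatrix(C, C), diag(3))
  expect_equal(diag(similarityMatrix(C, -C)), rep(-1, 3))
  # 2x2 hand case
  C2 <- rbind(c(1, 0), c(0, 1))
  T2 <- rbind(c(1, 1) / sqrt(2), c(0, 1))
  expect_equal(similarityMatrix(C2, T2),
               rbind(c(0.7071, 0), c(0.7071, 1)), tolerance = 1e-4)
  expect_error(similarityMatrix(rbind(c(0, 0)), T2), "zero-norm")
})

test_that("contrastive loss has its closed-form values", {
  expect_equal(contrastiveLoss(matrix(0.3, 4, 4)), log(4))   # uniform
  expect_equal(contrastiveLoss(matrix(5, 1, 1)), 0)          # K = 1
  expect_equal(contrastiveLoss(diag(10, 2), temperature = 1),
               log(1 + exp(-10)), tolerance = 1e-9)
  expect_error(contrastiveLoss(matrix(0, 2, 3)), "square")
  expect_error(contrastiveLoss(matrix(0, 2, 2), temperature = 0), "positive")
})

test_that("loss matches an independent softmax cross-entropy oracle", {
  oracle <- function(sim, tau) {
    K <- nrow(sim)
    ceRow <- function(M) {
      tot <- 0
      for (i in seq_len(K)) {
        p <- exp(M[i, ] / tau) / sum(exp(M[i, ] / tau))
        tot <- tot - log(p[i])
      }
      tot / K
    }
    (ceRow(sim) + ceRow(t(sim))) / 2
  }
  set.seed(31)
  for (trial in 1:100) {
    sim <- matrix(runif(9, -1, 1), 3, 3)
    tau <- runif(1, 0.05, 2)
    expect_equal(contrastiveLoss(sim, tau), oracle(sim, tau),
                 tolerance = 1e-6)
  }
})

test_that("loss is rotation-invariant and monotone in the diagonal", {
  ns <- asNamespace("scPathAlign")
  set.seed(8)
  C <- matrix(rnorm(12), 4, 3)
  T_ <- matrix(rnorm(12), 4, 3)
  base <- contrastiveLoss(similarityMatrix(C, T_), 0.5)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))          # random rotation
  expect_equal(contrastiveLoss(similarityMatrix(C %*% R, T_ %*% R), 0.5),
               base, tolerance = 1e-10)
  sim <- matrix(runif(16, -1, 1), 4, 4)
  for (i in 1:4) {
    bumped <- sim
    bumped[i, i] <- bumped[i, i] + 0.2
    expect_lte(contrastiveLoss(bumped, 0.7), contrastiveLoss(sim, 0.7))
  }
})

test_that("batches contain exactly K cells with pairwise-distinct names", {
  nms <- rep(c("a", "b", "c", "d"), times = c(5, 1, 10, 3))
  set.seed(2)
  idx <- sampleBatch(nms, 4L)
  expect_length(idx, 4L)
  expect_setequal(nms[idx], c("a", "b", "c", "d"))   # K = n distinct
  set.seed(7); b1 <- sampleBatch(nms, 3L)
  set.seed(7); b2 <- sampleBatch(nms, 3L)
  expect_identical(b1, b2)
  expect_error(sampleBatch(nms, 5L), "batch size")
})

test_that("name selection frequencies are uniform over many batches", {
  nms <- rep(c("a", "b", "c", "d", "e"), times = c(2, 20, 5, 40, 8))
  set.seed(123)
  picks <- table(unlist(replicate(1200, nms[sampleBatch(nms, 2L)],
                                  simplify = FALSE)))
  # each name expected 1200*2/5 = 480 times regardless of its cell count
  expect_gt(stats::chisq.test(picks)$p.value, 0.001)
})

test_that("training starts near ln K, descends, and is seed-reproducible", {
  sm <- smallTrainingSet()
  # step-0 loss at temperature 1: similarities are near-uniform at init
  cfg1 <- tinyRunConfig(batchSize = 6L, temperature = 1)
  m1 <- trainAlignment(sm$pp, sm$grouping, cfg1, steps = 1L, seed = 3L)
  expect_lt(abs(lossTrace(m1)[1] - log(6)) / log(6), 0.2)
  # sustained training at the desk temperature more than halves the loss
  cfg <- tinyRunConfig(batchSize = 6L)
  mA <- trainAlignment(sm$pp, sm$grouping, cfg, steps = 250L, seed = 3L)
  tr <- lossTrace(mA)
  expect_lt(mean(utils::tail(tr, 20)), 0.5 * mean(utils::head(tr, 5)))
  mB <- trainAlignment(sm$pp, sm$grouping, cfg, steps = 250L, seed = 3L)
  expect_identical(lossTrace(mA), lossTrace(mB))
})

test_that("validation checkpoint selection stores the selected score", {
  sm <- smallTrainingSet()
  cfg <- tinyRunConfig(batchSize = 6L)
  val <- sm$pp[seq(1, nrow(exprValues(sm$pp)), by = 7L), ]
  model <- trainAlignment(sm$pp, sm$grouping, cfg, steps = 60L, seed = 3L,
                          validation = val, evalEvery = 20L)
  expect_length(model@valScore, 1L)
  expect_gte(model@valScore, 0)
  expect_lte(model@valScore, 1)
  expect_error(trainAlignment(sm$pp, sm$grouping, cfg, steps = 10L,
                              restarts = 2L),
               "validation")
})
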