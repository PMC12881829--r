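# independent confusion-matrix oracle used in several blocks
oracleF1 <- function(predicted, truth, average) {
  classes <- sort(union(predicted, truth))
  tp <- fp <- fn <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp[cl] <- sum(predicted == cl & truth == cl)
    fp[cl] <- sum(predicted == cl & truth != cl)
    fn[cl] <- sum(predicted != cl & truth == cl)
  }
  if (average == "micro")
    return(sum(tp) / (sum(tp) + 0.5 * (sum(fp) + sum(fn))))
  f1 <- ifelse(tp + fp + fn == 0, 0, tp / (tp + 0.5 * (fp + fn)))
  support <- vapply(classes, function(cl) sum(truth == cl), 1.0)
  sum(f1 * support) / sum(support)
}

test_that("F1 scores cover the exact endpoint cases", {
  expect_equal(f1Scores(c("a", "b"), c("a", "b"), "micro"), 1)
  expect_equal(f1Scores(c("a", "b"), c("a", "b"), "weighted_macro"), 1)
  expect_equal(f1Scores(c("b", "a"), c("a", "b"), "micro"), 0)
  expect_error(f1Scores(character(0), character(0)), "non-empty")
})

test_that("F1 matches the confusion-matrix oracle on a 3-class hand case", {
  truth <- c("a", "a", "a", "b", "b", "c")
  pred <- c("a", "b", "c", "b", "b", "a")
  for (avg in c("micro", "weighted_macro"))
    expect_equal(f1Scores(pred, truth, avg), oracleF1(pred, truth, avg),
                 tolerance = 1e-12)
})

test_that("micro-F1 equals accuracy and weighted macro matches its oracle", {
  set.seed(77)
  for (trial in 1:200) {
    n <- sample(10:60, 1)
    truth <- sample(letters[1:5], n, replace = TRUE)
    pred <- sample(letters[1:5], n, replace = TRUE)
    expect_equal(f1Scores(pred, truth, "micro"), mean(pred == truth),
                 tolerance = 1e-9)
    expect_equal(f1Scores(pred, truth, "weighted_macro"),
                 oracleF1(pred, truth, "weighted_macro"), tolerance = 1e-9)
  }
})

test_that("split scores partition by truth, never by prediction", {
  truth <- c("s1", "s1", "u1", "u1")
  pred <- c("u1", "s1", "s1", "u1")        # first cell predicted unseen
  sp <- splitScores(pred, truth, "s1")
  expect_equal(sp$seen$micro, 0.5)         # both seen-truth cells counted
  expect_equal(sp$unseen$micro, 0.5)
  allSeen <- splitScores(c("s1", "s1"), c("s1", "s1"), "s1")
  expect_true(is.na(allSeen$unseen$micro))
})

test_that("mixed F1 is the harmonic mean with the zero convention", {
  expect_equal(mixedF1(0.7, 0.7), 0.7)
  expect_equal(mixedF1(0.6, 0.3), 0.4)
  expect_equal(mixedF1(0.9, 0), 0)
  expect_equal(mixedF1(0, 0), 0)
  expect_true(is.na(mixedF1(NA_real_, 0.5)))
})

test_that("the entropy-bin curve bins evenly and respects sorting", {
  expect_equal(entropyBinCurve(runif(100), rep(TRUE, 100), 10L), rep(1, 10))
  # 100 cells, 100 bins: one cell per bin
  ent <- seq(0, 1, length.out = 100)
  seen <- rep(c(TRUE, FALSE), 50)
  curve <- entropyBinCurve(ent, seen, 100L)
  expect_true(all(curve %in% c(0, 1)))
  expect_identical(curve, as.numeric(seen))
  # perfectly separating entropy gives a step function
  ent2 <- c(runif(60, 0, 0.4), runif(40, 0.6, 1))
  seen2 <- c(rep(TRUE, 60), rep(FALSE, 40))
  curve2 <- entropyBinCurve(ent2, seen2, 10L)
  expect_identical(curve2, c(rep(1, 6), rep(0, 4)))
  # uneven division: first n %% bins bins get the extra cell
  curve3 <- entropyBinCurve(seq_len(7), c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                          FALSE, FALSE), 3L)
  expect_equal(curve3, c(2 / 3, 1 / 2, 0))    # bins of size 3, 2, 2
  expect_error(entropyBinCurve(1:5, rep(TRUE, 5), 10L), "bins")
})

test_that("entropy ties are broken by cell order", {
  ent <- rep(0.5, 6)
  seen <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_identical(entropyBinCurve(ent, seen, 2L), c(1, 0))
})

test_that("per-type accuracy conserves the total correct count", {
  truth <- c("a", "a", "b", "b", "b", "c")
  pred <- c("a", "b", "b", "b", "c", "c")
  acc <- perTypeAccuracy(pred, truth)
  expect_equal(acc[["a"]], 0.5)
  expect_equal(acc[["c"]], 1)
  support <- table(truth)[names(acc)]
  expect_equal(sum(acc * support), sum(pred == truth))
})

test_that("evaluateAnnotation assembles a coherent report", {
  sims <- matrix(runif(12), 4, 3)
  p <- new("PredictionSet", cellIds = sprintf("c%d", 1:4),
           candidates = c("s1", "s2", "u1"), seenSet = c("s1", "s2"),
           similarities = sims,
           probabilities = matrix(1 / 3, 4, 3),
           seenEntropy = c(0.1, 0.2, 0.6, 0.7),
           predictedName = c("s1", "s2", "u1", "u1"),
           oodFlag = c(FALSE, FALSE, TRUE, TRUE),
           finalName = c("s1", "s2", "u1", "u1"),
           threshold = 0.4)
  truth <- c("s1", "s2", "u1", "s2")
  rep <- evaluateAnnotation(p, truth, nBins = 2L)
  expect_equal(rep$micro_f1, 0.75)
  expect_equal(rep$mixed$micro,
               mixedF1(rep$seen$micro, rep$unseen$micro))
  expect_equal(rep$entropy_bins, c(1, 0.5))
})
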