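blobs <- function(n = 30, sep = 8, seed = 4) {
  set.seed(seed)
  rbind(matrix(rnorm(n * 2), n, 2),
        matrix(rnorm(n * 2, mean = sep), n, 2))
}

test_that("feature augmentation concatenates without rescaling", {
  X <- matrix(rnorm(50), 10, 5)
  P <- matrix(1 / 4, 10, 4)
  A <- augmentFeatures(X, P)
  expect_equal(dim(A), c(10L, 9L))
  expect_equal(unname(rowSums(A[, 6:9])), rep(1, 10))
  expect_identical(A[, 1:5], X)
  expect_error(augmentFeatures(X, P[1:5, ]), "same number")
  expect_error(augmentFeatures(X, P * 2), "sum to 1")
})

test_that("a constant probability block leaves k-means partitions unchanged", {
  X <- blobs()
  P <- matrix(1 / 3, nrow(X), 3)
  base <- kmeansCluster(X, 2L, seed = 5L)
  aug <- kmeansCluster(augmentFeatures(X, P), 2L, seed = 5L)
  # identical pairwise geometry up to a constant block -> same partition
  expect_equal(clusteringAccuracy(aug, base), 1.0)
})

test_that("k-means is seeded, bounded by n, and separates blobs", {
  X <- blobs()
  truth <- rep(c("p", "q"), each = 30)
  cl <- kmeansCluster(X, 2L, seed = 7L)
  expect_equal(clusteringAccuracy(cl, truth), 1.0)
  expect_identical(cl, kmeansCluster(X, 2L, seed = 7L))
  tinyX <- X[1:3, ]
  expect_length(unique(kmeansCluster(tinyX, 3L, seed = 1L)), 3L)
  expect_error(kmeansCluster(tinyX, 4L, seed = 1L), "exceeds")
})

test_that("Leiden clustering separates blobs deterministically", {
  X <- blobs(n = 40)
  truth <- rep(c("p", "q"), each = 40)
  cl <- leidenCluster(X, nNeighbors = 10L, resolution = 1.0, seed = 3L)
  expect_gte(length(unique(cl)), 2L)
  # communities never straddle the two blobs
  expect_equal(clusteringAccuracy(cl, truth) +
                 sum(table(cl, truth) == 0) * 0, clusteringAccuracy(cl, truth))
  crossTab <- table(cl, truth)
  expect_true(all(rowSums(crossTab > 0) == 1L))
  expect_identical(cl, leidenCluster(X, nNeighbors = 10L, seed = 3L))
  expect_error(leidenCluster(X[1:5, ], nNeighbors = 10L), "smaller")
})

test_that("community count does not increase as resolution decreases", {
  X <- blobs(n = 25, sep = 5)
  counts <- vapply(c(2, 1, 0.5, 0.1), function(res)
    length(unique(leidenCluster(X, nNeighbors = 8L, resolution = res,
                                seed = 2L))), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering accuracy solves the assignment problem exactly", {
  # identical partition up to labels
  truth <- rep(c("a", "b", "c"), times = c(4, 3, 5))
  perm <- c(a = 3, b = 1, c = 2)
  expect_equal(clusteringAccuracy(perm[truth], truth), 1.0)
  # single cluster over 2 balanced classes
  expect_equal(clusteringAccuracy(rep(1, 10), rep(c("a", "b"), 5)), 0.5)
  # brute-force over all cluster-to-class bijections on random 3-cluster cases
  bruteAcc <- function(cl, truth) {
    tab <- table(cl, truth)
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                  c(3, 2, 1))
    best <- 0
    for (p in perms) {
      tot <- sum(tab[cbind(1:min(3, nrow(tab)),
                           p[seq_len(min(3, nrow(tab)))])])
      best <- max(best, tot)
    }
    best / length(cl)
  }
  set.seed(10)
  for (trial in 1:25) {
    cl <- sample(1:3, 30, replace = TRUE)
    truth <- sample(c("x", "y", "z"), 30, replace = TRUE)
    expect_equal(clusteringAccuracy(cl, truth), bruteAcc(cl, truth),
                 info = paste("trial", trial))
  }
})

test_that("accuracy is invariant to cluster relabeling and uneven counts", {
  set.seed(3)
  cl <- sample(1:4, 40, replace = TRUE)
  truth <- sample(c("a", "b"), 40, replace = TRUE)   # more clusters than classes
  relabeled <- c(9, 2, 7, 5)[cl]
  expect_equal(clusteringAccuracy(cl, truth),
               clusteringAccuracy(relabeled, truth))
})

test_that("the Hungarian solver matches brute force on random costs", {
  ns <- asNamespace("scPathAlign")
  bruteBest <- function(cost) {
    n <- nrow(cost)
    perms <- combinat_perms(n)
    min(vapply(perms, function(p) sum(cost[cbind(1:n, p)]), 1.0))
  }
  combinat_perms <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (i in seq_len(n))
      for (rest in combinat_perms(n - 1L))
        out[[length(out) + 1L]] <- c(i, ifelse(rest >= i, rest + 1L, rest))
    out
  }
  set.seed(14)
  for (n in c(2, 3, 4, 5)) {
    for (trial in 1:5) {
      cost <- matrix(runif(n * n, 0, 10), n, n)
      a <- ns$.hungarian(cost)
      expect_equal(sum(cost[cbind(1:n, a)]), bruteBest(cost),
                   tolerance = 1e-9)
    }
  }
})
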