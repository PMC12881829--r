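#' Augment expression features with model probabilities
#'
#' Concatenates the per-cell softmax-normalized prediction probabilities
#' to the expression features column-wise, with no rescaling of either
#' block.
#'
#' @param expression an \linkS4class{ExpressionMatrix} or a plain
#'   cells x genes matrix.
#' @param probabilities cells x candidates matrix whose rows sum to 1
#'   (within 1e-6).
#' @return A cells x (genes + candidates) numeric matrix.
#' @export
augmentFeatures <- function(expression, probabilities) {
  X <- if (is(expression, "ExpressionMatrix")) exprValues(expression)
       else as.matrix(expression)
  probabilities <- as.matrix(probabilities)
  if (nrow(X) != nrow(probabilities))
    stop("expression and probabilities must have the same number of cells")
  if (max(abs(rowSums(probabilities) - 1)) > 1e-6)
    stop("probability rows must sum to 1")
  cbind(X, probabilities)
}

#' Seeded K-Means clustering
#'
#' Standard k-means (\code{stats::kmeans}) with seeded initialization and
#' multiple restarts.
#'
#' @param features cells x features numeric matrix.
#' @param k number of clusters (at most the number of cells).
#' @param seed integer seed.
#' @param nstart random restarts.
#' @return Integer cluster labels (1..k), one per cell.
#' @export
kmeansCluster <- function(features, k, seed = 1L, nstart = 10L) {
  features <- as.matrix(features)
  if (k > nrow(features))
    stop("k (", k, ") exceeds the number of cells (", nrow(features), ")")
  if (k == nrow(features)) return(seq_len(k))    # each cell its own cluster
  .withSeed(as.integer(seed),
            stats::kmeans(features, centers = k, nstart = nstart,
                          iter.max = 100L)$cluster)
}

#' Seeded Leiden clustering on a kNN graph
#'
#' Builds the Euclidean k-nearest-neighbour graph of the feature rows
#' (undirected union of neighbourhoods) and runs Leiden community
#' detection (modularity objective) at the given resolution.
#'
#' @param features cells x features numeric matrix.
#' @param nNeighbors neighbours per cell (default 15; must be below the
#'   cell count).
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed integer seed.
#' @return Integer community labels, one per cell.
#' @export
leidenCluster <- function(features, nNeighbors = 15L, resolution = 1.0,
                          seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (nNeighbors >= n) stop("nNeighbors must be smaller than the cell count")
  d <- as.matrix(stats::dist(features))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(nNeighbors + 1L)]
    cbind(i, nb)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (any(igraph::degree(g) == 0))
    stop("degenerate kNN graph: isolated cells")
  memb <- .withSeed(as.integer(seed),
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution,
                           n_iterations = 5L)$membership)
  as.integer(memb)
}

#' Clustering accuracy under optimal cluster-to-class assignment
#'
#' Matches clusters to true classes one-to-one so as to maximize the total
#' number of matched cells (the linear-assignment optimum, computed with
#' the Hungarian algorithm) and returns matched / total. When the cluster
#' and class counts differ, the assignment runs over the smaller side and
#' unmatched clusters contribute nothing. Invariant to relabeling of
#' cluster ids.
#'
#' @param clusterLabels per-cell cluster assignments.
#' @param truthNames per-cell true class names.
#' @return Accuracy in [0, 1].
#' @export
clusteringAccuracy <- function(clusterLabels, truthNames) {
  if (length(clusterLabels) != length(truthNames))
    stop("label vectors must have equal length")
  tab <- table(clusterLabels, truthNames)
  counts <- matrix(as.numeric(tab), nrow(tab), ncol(tab))
  nSide <- max(dim(counts))
  padded <- matrix(0, nSide, nSide)
  padded[seq_len(nrow(counts)), seq_len(ncol(counts))] <- counts
  assignment <- .hungarian(max(padded) - padded)
  matched <- sum(padded[cbind(seq_len(nSide), assignment)])
  matched / length(clusterLabels)
}

# Hungarian algorithm, O(n^3) potentials formulation. cost: square matrix.
# Returns the column assigned to each row of the minimum-cost perfect
# matching.
.hungarian <- function(cost) {
  n <- nrow(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)        # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}
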