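#' Cosine similarity matrix between cell and name embeddings
#'
#' L2-normalizes the rows of both matrices and returns the K x K' matrix of
#' cosine similarities; entry (i, j) compares cell i with name j. The
#' stored embeddings themselves are left unnormalized.
#'
#' @param C cells x d matrix of projected cell embeddings.
#' @param T_ names x d matrix of projected name embeddings.
#' @return Matrix of cosines in [-1, 1].
#' @export
similarityMatrix <- function(C, T_) {
  C <- as.matrix(C); T_ <- as.matrix(T_)
  nC <- sqrt(rowSums(C * C))
  nT <- sqrt(rowSums(T_ * T_))
  if (any(nC == 0) || any(nT == 0))
    stop("zero-norm embedding row; cosine similarity undefined")
  (C / nC) %*% t(T_ / nT)
}

#' Symmetric contrastive cross-entropy loss
#'
#' The batch objective: given the K x K similarity matrix of K cells
#' against their K (distinct) names, scale by \code{1/temperature} and
#' average the softmax cross-entropy with diagonal targets over rows (each
#' cell classifies its name) and over columns (each name classifies its
#' cell). The loss is ln K for a constant matrix, 0 for K = 1, and tends
#' to 0 as the diagonal dominates.
#'
#' @param sim square similarity matrix with matching pairs on the
#'   diagonal.
#' @param temperature positive softmax temperature (default 1).
#' @return Scalar loss (nats).
#' @examples
#' contrastiveLoss(matrix(0, 3, 3))  # log(3)
#' @export
contrastiveLoss <- function(sim, temperature = 1) {
  .contrastiveCheck(sim, temperature)
  .contrastiveLossGrad(sim, temperature, grad = FALSE)$loss
}

.contrastiveCheck <- function(sim, temperature) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim))
    stop("similarity matrix must be square (K x K)")
  if (temperature <= 0) stop("temperature must be positive")
}

.contrastiveLossGrad <- function(sim, temperature, grad = TRUE) {
  K <- nrow(sim)
  lg <- sim / temperature
  ceDir <- function(L) {
    mx <- apply(L, 1L, max)
    lse <- log(rowSums(exp(L - mx))) + mx
    mean(lse - diag(L))
  }
  loss <- (ceDir(lg) + ceDir(t(lg))) / 2
  if (!grad) return(list(loss = loss))
  I <- diag(K)
  Pr <- .softmaxRows(lg)
  Pc <- .softmaxRows(t(lg))
  dsim <- ((Pr - I) / K + t(Pc - I) / K) / (2 * temperature)
  list(loss = loss, dsim = dsim)
}

# loss + gradients w.r.t. the unnormalized embeddings C and T
.contrastiveBackward <- function(C, T_, temperature) {
  nC <- sqrt(rowSums(C * C))
  nT <- sqrt(rowSums(T_ * T_))
  if (any(nC == 0) || any(nT == 0)) stop("zero-norm embedding row")
  Cn <- C / nC
  Tn <- T_ / nT
  sim <- Cn %*% t(Tn)
  lg <- .contrastiveLossGrad(sim, temperature)
  dCn <- lg$dsim %*% Tn
  dTn <- t(lg$dsim) %*% Cn
  dC <- (dCn - Cn * rowSums(dCn * Cn)) / nC
  dT <- (dTn - Tn * rowSums(dTn * Tn)) / nT
  list(loss = lg$loss, dC = dC, dT = dT, sim = sim)
}

#' Sample a batch of cells with pairwise-distinct names
#'
#' Draws K cell-type names uniformly without replacement from the distinct
#' names present, then one cell uniformly from each chosen name. Uses the
#' caller's RNG stream, so results are reproducible under
#' \code{set.seed}.
#'
#' @param cellNames character vector of per-cell names.
#' @param K batch size; at most the number of distinct names.
#' @return Integer vector of K cell indices.
#' @export
sampleBatch <- function(cellNames, K) {
  uniq <- unique(cellNames)
  if (length(uniq) < K)
    stop("only ", length(uniq), " distinct cell names; use a batch size K <= ",
         length(uniq))
  chosen <- sample(uniq, K)
  vapply(chosen, function(nm) {
    cand <- which(cellNames == nm)
    cand[sample.int(length(cand), 1L)]
  }, 1L)
}

#' Contrastive alignment training
#'
#' Jointly optimizes the expression encoder, both projection heads and
#' (unless frozen or adapter-backed) the built-in text encoder by Adam on
#' the symmetric contrastive loss. Each step samples a batch of
#' \code{config@batchSize} cells with pairwise-distinct names, optionally
#' zeroes a random fraction \code{config@maskRate} of the batch's
#' expression values (input-masking augmentation), encodes both
#' modalities, projects into the shared space and descends the batch-wise
#' K x K objective. Fully seeded: identical inputs and seed give identical
#' loss traces.
#'
#' When a \code{validation} matrix is supplied, the model is scored every
#' \code{evalEvery} steps by prediction accuracy on the validation cells
#' (candidates = the training names) and the best checkpoint is returned
#' (ties favour the later checkpoint). With \code{restarts > 1}, that many
#' independently initialized runs are trained and the one with the best
#' validation score is kept.
#'
#' @param m a labeled \linkS4class{ExpressionMatrix} in
#'   \code{normalized_log} state.
#' @param grouping a \linkS4class{GeneGrouping} over the matrix genes.
#' @param config a \linkS4class{RunConfig}; \code{lrContrastive},
#'   \code{batchSize}, \code{temperature}, \code{dropout} and
#'   \code{maskRate} are used.
#' @param steps number of optimization steps.
#' @param seed integer seed for initialization, batch sampling, masking
#'   and dropout.
#' @param validation optional labeled \linkS4class{ExpressionMatrix} for
#'   checkpoint selection.
#' @param evalEvery validation interval in steps.
#' @param restarts number of random restarts (requires
#'   \code{validation} when > 1).
#' @param adapter optional external text encoder (see
#'   \code{\link{initModel}}).
#' @param freezeText if TRUE the built-in token table is not updated (only
#'   the text projection trains).
#' @param verbose print the loss every 50 steps.
#' @return A trained \linkS4class{AlignmentModel} with its per-step loss
#'   trace (and validation score, when selection was used).
#' @export
trainAlignment <- function(m, grouping, config = tinyRunConfig(),
                           steps = 300L, seed = config@seed,
                           validation = NULL, evalEvery = 250L,
                           restarts = 1L, adapter = NULL,
                           freezeText = FALSE, verbose = FALSE) {
  .checkState(m, "normalized_log", "trainAlignment")
  nms <- cellNames(m)
  if (!length(nms)) stop("trainAlignment requires labeled cells")
  if (restarts > 1L && is.null(validation))
    stop("restarts > 1 requires a validation set to choose between runs")
  if (restarts > 1L) {
    runs <- lapply(seq_len(restarts), function(r) {
      trainAlignment(m, grouping, config, steps,
                     seed = as.integer(seed) + 1000L * (r - 1L),
                     validation = validation, evalEvery = evalEvery,
                     restarts = 1L, adapter = adapter,
                     freezeText = freezeText, verbose = verbose)
    })
    scores <- vapply(runs, function(x) x@valScore, 1.0)
    return(runs[[which.max(scores)]])
  }
  X <- .alignToVocabulary(m, grouping)
  K <- config@batchSize
  model <- initModel(grouping, nms, config, adapter = adapter, seed = seed)
  params <- model@params
  adam <- .adamInit(params)
  trace <- numeric(steps)
  tokenCache <- NULL
  if (model@textKind == "builtin") {
    tokenCache <- .tokenIdsFor(unique(nms), model@textVocab)
    names(tokenCache) <- unique(nms)
  }
  best <- NULL
  trainNames <- unique(nms)

  set.seed(as.integer(seed) + 1L)
  for (step in seq_len(steps)) {
    idx <- sampleBatch(nms, K)
    Xb <- X[idx, , drop = FALSE]
    if (config@maskRate > 0)
      Xb[matrix(stats::runif(length(Xb)) < config@maskRate, nrow(Xb))] <- 0
    batchNames <- nms[idx]
    enc <- .encForward(params, Xb, grouping@groups, config,
                       dropout = config@dropout)
    Cp <- .addB(enc$cls %*% params$projE$W, params$projE$b)
    if (model@textKind == "adapter") {
      tEmb <- adapter(batchNames)
    } else {
      ids <- tokenCache[batchNames]
      tEmb <- .textEmbed(params$text$emb, ids)
    }
    Tp <- .addB(tEmb %*% params$text$projW, params$text$projb)

    cb <- .contrastiveBackward(Cp, Tp, config@temperature)
    if (!is.finite(cb$loss))
      stop("non-finite loss at step ", step,
           "; lower the learning rate or temperature")
    trace[step] <- cb$loss
    if (verbose && step %% 50L == 0L)
      message(sprintf("step %d  loss %.4f", step, cb$loss))

    grads <- .treeZero(params)
    grads$projE$W <- t(enc$cls) %*% cb$dC
    grads$projE$b <- colSums(cb$dC)
    dcls <- cb$dC %*% t(params$projE$W)
    encG <- .encBackward(params, enc$cache, dcls)
    grads$gene <- encG$gene; grads$cls <- encG$cls
    grads$layers <- encG$layers
    grads$text$projW <- t(tEmb) %*% cb$dT
    grads$text$projb <- colSums(cb$dT)
    if (model@textKind == "builtin" && !freezeText) {
      dTemb <- cb$dT %*% t(params$text$projW)
      grads$text$emb <- .textEmbedBackward(params$text$emb, ids, dTemb)
    }
    upd <- .adamStep(params, grads, adam, config@lrContrastive)
    params <- upd$params
    adam <- upd$state

    if (!is.null(validation) &&
        (step %% evalEvery == 0L || step == steps)) {
      model@params <- params
      pv <- predictCells(model, validation, trainNames)
      sc <- mean(pv@predictedName == cellNames(validation))
      if (is.null(best) || sc >= best$score)
        best <- list(score = sc, params = params)
    }
  }
  if (!is.null(best)) {
    model@params <- best$params
    model@valScore <- best$score
  } else {
    model@params <- params
  }
  model@lossTrace <- trace
  model
}

#' Supervised classifier training
#'
#' Trains the pathway-token transformer with a linear classification head
#' by Adam on softmax cross-entropy against the labeled cell types (the
#' supervised annotation setting). Batches are sampled uniformly (labels
#' may repeat within a batch).
#'
#' @inheritParams trainAlignment
#' @param steps optimization steps.
#' @return A trained \linkS4class{AlignmentModel} whose \code{classes}
#'   slot holds the label set of the head.
#' @export
trainClassifier <- function(m, grouping, config = tinyRunConfig(),
                            steps = 200L, seed = config@seed,
                            verbose = FALSE) {
  .checkState(m, "normalized_log", "trainClassifier")
  nms <- cellNames(m)
  if (!length(nms)) stop("trainClassifier requires labeled cells")
  classes <- sort(unique(nms))
  if (length(classes) < 2L) stop("need at least 2 classes")
  y <- match(nms, classes)
  X <- .alignToVocabulary(m, grouping)
  K <- min(config@batchSize, nrow(X))
  model <- initModel(grouping, nms, config, classes = classes, seed = seed)
  params <- model@params
  adam <- .adamInit(params)
  trace <- numeric(steps)

  set.seed(as.integer(seed) + 1L)
  for (step in seq_len(steps)) {
    idx <- sample.int(nrow(X), K)
    Xb <- X[idx, , drop = FALSE]
    if (config@maskRate > 0)
      Xb[matrix(stats::runif(length(Xb)) < config@maskRate, nrow(Xb))] <- 0
    enc <- .encForward(params, Xb, grouping@groups,
                       config, dropout = config@dropout)
    logits <- .addB(enc$cls %*% params$head$W, params$head$b)
    P <- .softmaxRows(logits)
    picked <- cbind(seq_len(K), y[idx])
    loss <- -mean(log(pmax(P[picked], 1e-300)))
    if (!is.finite(loss)) stop("non-finite loss at step ", step)
    trace[step] <- loss
    if (verbose && step %% 50L == 0L)
      message(sprintf("step %d  loss %.4f", step, loss))

    dLogits <- P
    dLogits[picked] <- dLogits[picked] - 1
    dLogits <- dLogits / K
    grads <- .treeZero(params)
    grads$head$W <- t(enc$cls) %*% dLogits
    grads$head$b <- colSums(dLogits)
    encG <- .encBackward(params, enc$cache, dLogits %*% t(params$head$W))
    grads$gene <- encG$gene; grads$cls <- encG$cls
    grads$layers <- encG$layers
    upd <- .adamStep(params, grads, adam, config@lrPretrain)
    params <- upd$params
    adam <- upd$state
  }
  model@params <- params
  model@lossTrace <- trace
  model
}
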