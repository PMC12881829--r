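# Hand-implemented transformer encoder with explicit backpropagation.
#
# The model is small enough (desk-scale: D=32, 2 layers; production
# documented at 768/12) that dense base-R linear algebra is adequate. A
# batch of K cells is processed as one (K*(M+1)) x D row-block matrix so
# that layer norms, linear maps and the feed-forward block are single
# matrix operations; only the attention softmax runs per cell and head.
# Gradients are verified against finite differences in the test suite.

.addB <- function(M, b) M + rep(b, each = nrow(M))

# layer norm over rows
.lnF <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  isd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * isd
  n <- nrow(x)
  list(y = xhat * rep(g, each = n) + rep(b, each = n), xhat = xhat, isd = isd)
}

.lnB <- function(dy, lnc, g) {
  n <- nrow(dy)
  dxhat <- dy * rep(g, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * lnc$xhat)
  list(dx = (dxhat - m1 - lnc$xhat * m2) * lnc$isd,
       dg = colSums(dy * lnc$xhat), db = colSums(dy))
}

.softmaxRows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

.dropMask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

# ---- parameter initialization -------------------------------------------

# Weight matrices are drawn with sd 1/sqrt(fan_in) so activations keep
# unit-order scale through the stack regardless of D; embedding tables use
# sd 0.5 so token magnitudes stay informative relative to the CLS vector.
.initParams <- function(cfg, vocabSize, textVocabSize, nClasses = 0L) {
  D <- cfg@embeddingDim; I <- cfg@intermediateDim
  S <- cfg@sharedDim; Dt <- cfg@textDim
  rn <- function(nr, nc, sd = 1 / sqrt(nr))
    matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  layer <- function() list(
    ln1g = rep(1, D), ln1b = rep(0, D),
    Wq = rn(D, D), bq = rep(0, D), Wk = rn(D, D), bk = rep(0, D),
    Wv = rn(D, D), bv = rep(0, D), Wo = rn(D, D), bo = rep(0, D),
    ln2g = rep(1, D), ln2b = rep(0, D),
    W1 = rn(D, I), b1 = rep(0, I), W2 = rn(I, D), b2 = rep(0, D))
  p <- list(
    gene = rn(vocabSize, D, sd = 0.5),
    cls  = stats::rnorm(D, sd = 0.5),
    layers = lapply(seq_len(cfg@nLayers), function(i) layer()),
    projE = list(W = rn(D, S), b = rep(0, S)),
    text = list(emb = rn(textVocabSize, Dt, sd = 0.5),
                projW = rn(Dt, S), projb = rep(0, S)))
  if (nClasses > 0L)
    p$head <- list(W = rn(D, nClasses), b = rep(0, nClasses))
  p
}

# ---- parameter-tree utilities -------------------------------------------

.treeMap <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) .treeMap(f, x))
    names(out) <- names(a)
    out
  } else f(a)
}

.treeMap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .treeMap2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

.treeZero <- function(a) .treeMap(function(x) x * 0, a)

.treeAdd <- function(a, b) .treeMap2(`+`, a, b)

# ---- Adam ---------------------------------------------------------------

.adamInit <- function(params)
  list(m = .treeZero(params), v = .treeZero(params), t = 0L)

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      rp <- p; rm <- m; rv <- v
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        rp[[i]] <- r[[1]]; rm[[i]] <- r[[2]]; rv[[i]] <- r[[3]]
      }
      list(rp, rm, rv)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      mh <- m2 / (1 - beta1^t)
      vh <- v2 / (1 - beta2^t)
      list(p - lr * mh / (sqrt(vh) + eps), m2, v2)
    }
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r[[1]], state = list(m = r[[2]], v = r[[3]], t = t))
}

# ---- encoder forward ----------------------------------------------------

# X: K x V normalized-log expression; groupIdx: list of index vectors.
# dropout > 0 draws masks from the current RNG stream (training only).
.encForward <- function(params, X, groupIdx, cfg, dropout = 0) {
  K <- nrow(X); M <- length(groupIdx); Tn <- M + 1L
  D <- cfg@embeddingDim; H <- cfg@nHeads; dh <- D %/% H
  scale <- 1 / sqrt(dh)
  clsRows <- seq(1L, K * Tn, by = Tn)
  rowsOf <- lapply(seq_len(K), function(k) ((k - 1L) * Tn + 1L):(k * Tn))
  colsOf <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))

  S <- matrix(0, K * Tn, D)
  S[clsRows, ] <- rep(params$cls, each = K)
  for (m in seq_len(M)) {
    idx <- groupIdx[[m]]
    S[clsRows + m, ] <- (X[, idx, drop = FALSE] %*%
                           params$gene[idx, , drop = FALSE]) / length(idx)
  }

  # post-norm (BERT-style) blocks: S <- LN(S + MHA(S)); S <- LN(S + FFN(S)).
  # No layer norm is applied to the input token embeddings themselves:
  # token magnitude carries the pathway-activity signal and the first
  # attention layer must be able to read it.
  layers <- vector("list", cfg@nLayers)
  for (l in seq_len(cfg@nLayers)) {
    p <- params$layers[[l]]
    Q <- .addB(S %*% p$Wq, p$bq)
    Km <- .addB(S %*% p$Wk, p$bk)
    V <- .addB(S %*% p$Wv, p$bv)
    P <- array(0, c(Tn, Tn, H, K))
    O <- matrix(0, K * Tn, D)
    for (k in seq_len(K)) {
      rows <- rowsOf[[k]]
      for (h in seq_len(H)) {
        cols <- colsOf[[h]]
        Sc <- (Q[rows, cols, drop = FALSE] %*%
                 t(Km[rows, cols, drop = FALSE])) * scale
        Pk <- .softmaxRows(Sc)
        P[, , h, k] <- Pk
        O[rows, cols] <- Pk %*% V[rows, cols, drop = FALSE]
      }
    }
    attnOut <- .addB(O %*% p$Wo, p$bo)
    mask1 <- .dropMask(K * Tn, D, dropout)
    if (!is.null(mask1)) attnOut <- attnOut * mask1
    A <- .lnF(S + attnOut, p$ln1g, p$ln1b)
    H1 <- .addB(A$y %*% p$W1, p$b1)
    Phi <- stats::pnorm(H1)
    Hg <- H1 * Phi                       # exact GELU
    Fo <- .addB(Hg %*% p$W2, p$b2)
    mask2 <- .dropMask(K * Tn, D, dropout)
    if (!is.null(mask2)) Fo <- Fo * mask2
    B <- .lnF(A$y + Fo, p$ln2g, p$ln2b)
    layers[[l]] <- list(Sin = S, Q = Q, Km = Km, V = V, P = P, O = O,
                        A = A, H1 = H1, Phi = Phi, Hg = Hg, B = B,
                        mask1 = mask1, mask2 = mask2)
    S <- B$y
  }
  list(cls = S[clsRows, , drop = FALSE],
       cache = list(X = X, groupIdx = groupIdx, layers = layers,
                    K = K, Tn = Tn, H = H, dh = dh, scale = scale,
                    clsRows = clsRows, rowsOf = rowsOf, colsOf = colsOf))
}

# ---- encoder backward ---------------------------------------------------

.encBackward <- function(params, cache, dcls) {
  K <- cache$K; Tn <- cache$Tn; H <- cache$H
  D <- ncol(dcls); scale <- cache$scale
  clsRows <- cache$clsRows; rowsOf <- cache$rowsOf; colsOf <- cache$colsOf

  g <- list(gene = matrix(0, nrow(params$gene), D),
            cls = numeric(D),
            layers = vector("list", length(params$layers)))

  dS <- matrix(0, K * Tn, D)
  dS[clsRows, ] <- dcls

  for (l in rev(seq_along(params$layers))) {
    p <- params$layers[[l]]
    cc <- cache$layers[[l]]
    # second norm: S_out = LN2(A_y + Fo)
    lb2 <- .lnB(dS, cc$B, p$ln2g)
    # feed-forward block
    dFo <- if (is.null(cc$mask2)) lb2$dx else lb2$dx * cc$mask2
    dHg <- dFo %*% t(p$W2)
    dW2 <- t(cc$Hg) %*% dFo
    db2 <- colSums(dFo)
    dH1 <- dHg * (cc$Phi + cc$H1 * stats::dnorm(cc$H1))
    dAy <- lb2$dx + dH1 %*% t(p$W1)
    dW1 <- t(cc$A$y) %*% dH1
    db1 <- colSums(dH1)
    # first norm: A_y = LN1(S_in + attnOut)
    lb1 <- .lnB(dAy, cc$A, p$ln1g)
    dAttn <- if (is.null(cc$mask1)) lb1$dx else lb1$dx * cc$mask1
    dO <- dAttn %*% t(p$Wo)
    dWo <- t(cc$O) %*% dAttn
    dbo <- colSums(dAttn)
    dQ <- matrix(0, K * Tn, D); dK <- matrix(0, K * Tn, D)
    dV <- matrix(0, K * Tn, D)
    for (k in seq_len(K)) {
      rows <- rowsOf[[k]]
      for (h in seq_len(H)) {
        cols <- colsOf[[h]]
        Pk <- cc$P[, , h, k]
        dOk <- dO[rows, cols, drop = FALSE]
        Vk <- cc$V[rows, cols, drop = FALSE]
        dP <- dOk %*% t(Vk)
        dV[rows, cols] <- t(Pk) %*% dOk
        dSc <- Pk * (dP - rowSums(Pk * dP))
        dQ[rows, cols] <- (dSc %*% cc$Km[rows, cols, drop = FALSE]) * scale
        dK[rows, cols] <- (t(dSc) %*% cc$Q[rows, cols, drop = FALSE]) * scale
      }
    }
    g$layers[[l]] <- list(
      ln1g = lb1$dg, ln1b = lb1$db,
      Wq = t(cc$Sin) %*% dQ, bq = colSums(dQ),
      Wk = t(cc$Sin) %*% dK, bk = colSums(dK),
      Wv = t(cc$Sin) %*% dV, bv = colSums(dV),
      Wo = dWo, bo = dbo,
      ln2g = lb2$dg, ln2b = lb2$db,
      W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    dS <- lb1$dx + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }

  g$cls <- colSums(dS[clsRows, , drop = FALSE])
  X <- cache$X
  for (m in seq_along(cache$groupIdx)) {
    idx <- cache$groupIdx[[m]]
    dZ <- dS[clsRows + m, , drop = FALSE]
    g$gene[idx, ] <- g$gene[idx, ] +
      (t(X[, idx, drop = FALSE]) %*% dZ) / length(idx)
  }
  g
}
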