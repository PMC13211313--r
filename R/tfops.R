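# Low-level transformer building blocks with explicit forward/backward
# passes. Batches are represented as row-stacked matrices ((B*T) x d) so all
# position-wise operations hit BLAS as single large matrix products; only the
# attention score products loop over samples (and heads), where the matrices
# are small. Caches returned by *_fwd feed the matching *_bwd.

# Linear layers are bias-free (biases add measurable broadcast cost in R and
# contribute little next to the layer norms' affine terms); the patch
# embedding keeps its bias via an explicit add in the caller.
.lin_fwd <- function(X, W) {
  list(Y = X %*% W, X = X)
}
.lin_bwd <- function(dY, cache, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(cache$X, dY))
}

.LN_EPS <- 1e-5

.ln_fwd <- function(X, g, b) {
  n <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  sd <- sqrt(v + .LN_EPS)
  xhat <- Xc / sd
  Y <- xhat * rep(g, each = n) + rep(b, each = n)
  list(Y = Y, xhat = xhat, sd = sd)
}
.ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) / cache$sd
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# ReLU feed-forward activation (the original-transformer choice; its
# gradient is a cached mask, which matters on a single CPU)
.act_fwd <- function(X) {
  M <- X > 0
  list(Y = X * M, M = M)
}
.act_bwd <- function(dY, cache) dY * cache$M

.softmax_rows <- function(S) {
  rmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - rmax)
  E / rowSums(E)
}

# Multi-head attention over a stacked batch. Xq is (B*Tq) x d, Xkv is
# (B*Tk) x d unless `shared_kv` is TRUE, in which case Xkv is a single Tk x d
# matrix whose keys/values are shared by every sample (used by beam decoding
# where all beams attend to one encoder memory).
.mha_fwd <- function(p, Xq, Xkv, B, Tq, Tk, n_heads, causal = FALSE,
                     shared_kv = FALSE, kv_cache = NULL) {
  d <- ncol(p$Wq)
  dh <- d %/% n_heads
  lq <- .lin_fwd(Xq, p$Wq)
  if (is.null(kv_cache)) {
    lk <- .lin_fwd(Xkv, p$Wk)
    lv <- .lin_fwd(Xkv, p$Wv)
  } else {
    # inference-only: keys/values precomputed once for a fixed memory
    lk <- list(Y = kv_cache$K)
    lv <- list(Y = kv_cache$V)
  }
  Q <- lq$Y; K <- lk$Y; V <- lv$Y
  Ctx <- matrix(0, nrow(Xq), d)
  A_cache <- vector("list", B)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rq <- ((b - 1L) * Tq + 1L):(b * Tq)
    rk <- if (shared_kv) seq_len(Tk) else ((b - 1L) * Tk + 1L):(b * Tk)
    Ab <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[rq, cols, drop = FALSE], K[rk, cols, drop = FALSE]) * scale
      if (causal) S[upper.tri(S)] <- -Inf
      A <- .softmax_rows(S)
      Ctx[rq, cols] <- A %*% V[rk, cols, drop = FALSE]
      Ab[[h]] <- A
    }
    A_cache[[b]] <- Ab
  }
  lo <- .lin_fwd(Ctx, p$Wo)
  list(Y = lo$Y, lq = lq, lk = lk, lv = lv, lo = lo, Q = Q, K = K, V = V,
       A = A_cache, B = B, Tq = Tq, Tk = Tk, n_heads = n_heads,
       shared_kv = shared_kv, scale = scale)
}

.mha_bwd <- function(dY, cache, p) {
  B <- cache$B; Tq <- cache$Tq; Tk <- cache$Tk
  n_heads <- cache$n_heads
  d <- ncol(p$Wq); dh <- d %/% n_heads
  go <- .lin_bwd(dY, cache$lo, p$Wo)
  dCtx <- go$dX
  Q <- cache$Q; K <- cache$K; V <- cache$V
  dQ <- matrix(0, nrow(Q), d)
  dK <- matrix(0, nrow(K), d)
  dV <- matrix(0, nrow(V), d)
  for (b in seq_len(B)) {
    rq <- ((b - 1L) * Tq + 1L):(b * Tq)
    rk <- if (cache$shared_kv) seq_len(Tk) else ((b - 1L) * Tk + 1L):(b * Tk)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[b]][[h]]
      dCtx_h <- dCtx[rq, cols, drop = FALSE]
      dA <- tcrossprod(dCtx_h, V[rk, cols, drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      dQ[rq, cols] <- (dS %*% K[rk, cols, drop = FALSE]) * cache$scale
      if (cache$shared_kv) {
        dV[rk, cols] <- dV[rk, cols] + crossprod(A, dCtx_h)
        dK[rk, cols] <- dK[rk, cols] + crossprod(dS, Q[rq, cols, drop = FALSE]) * cache$scale
      } else {
        dV[rk, cols] <- crossprod(A, dCtx_h)
        dK[rk, cols] <- crossprod(dS, Q[rq, cols, drop = FALSE]) * cache$scale
      }
    }
  }
  gq <- .lin_bwd(dQ, cache$lq, p$Wq)
  gk <- .lin_bwd(dK, cache$lk, p$Wk)
  gv <- .lin_bwd(dV, cache$lv, p$Wv)
  list(dXq = gq$dX, dXkv = gk$dX + gv$dX,
       grads = list(Wq = gq$dW, Wk = gk$dW, Wv = gv$dW, Wo = go$dW))
}

.ffn_fwd <- function(p, X) {
  l1 <- .lin_fwd(X, p$W1)
  g <- .act_fwd(l1$Y)
  l2 <- .lin_fwd(g$Y, p$W2)
  list(Y = l2$Y, l1 = l1, g = g, l2 = l2)
}
.ffn_bwd <- function(dY, cache, p) {
  g2 <- .lin_bwd(dY, cache$l2, p$W2)
  dg <- .act_bwd(g2$dX, cache$g)
  g1 <- .lin_bwd(dg, cache$l1, p$W1)
  list(dX = g1$dX, grads = list(W1 = g1$dW, W2 = g2$dW))
}

# One pre-norm encoder block: x + MHA(LN(x)), then x + FFN(LN(x)).
.enc_block_fwd <- function(p, X, B, T, n_heads) {
  n1 <- .ln_fwd(X, p$ln1$g, p$ln1$b)
  at <- .mha_fwd(p$attn, n1$Y, n1$Y, B, T, T, n_heads)
  X1 <- X + at$Y
  n2 <- .ln_fwd(X1, p$ln2$g, p$ln2$b)
  ff <- .ffn_fwd(p$ffn, n2$Y)
  list(Y = X1 + ff$Y, n1 = n1, at = at, n2 = n2, ff = ff)
}
.enc_block_bwd <- function(dY, cache, p) {
  fb <- .ffn_bwd(dY, cache$ff, p$ffn)
  n2b <- .ln_bwd(fb$dX, cache$n2, p$ln2$g)
  dX1 <- dY + n2b$dX
  ab <- .mha_bwd(dX1, cache$at, p$attn)
  n1b <- .ln_bwd(ab$dXq + ab$dXkv, cache$n1, p$ln1$g)
  list(dX = dX1 + n1b$dX,
       grads = list(ln1 = list(g = n1b$dg, b = n1b$db), attn = ab$grads,
                    ln2 = list(g = n2b$dg, b = n2b$db), ffn = fb$grads))
}

# One pre-norm decoder block: causal self-attention, cross-attention over the
# encoder memory, then the feed-forward sublayer.
.dec_block_fwd <- function(p, X, M, B, Td, Tm, n_heads, shared_kv = FALSE,
                           cross_kv = NULL) {
  n1 <- .ln_fwd(X, p$ln1$g, p$ln1$b)
  sa <- .mha_fwd(p$self, n1$Y, n1$Y, B, Td, Td, n_heads, causal = TRUE)
  X1 <- X + sa$Y
  n2 <- .ln_fwd(X1, p$ln2$g, p$ln2$b)
  ca <- .mha_fwd(p$cross, n2$Y, M, B, Td, Tm, n_heads, shared_kv = shared_kv,
                 kv_cache = cross_kv)
  X2 <- X1 + ca$Y
  n3 <- .ln_fwd(X2, p$ln3$g, p$ln3$b)
  ff <- .ffn_fwd(p$ffn, n3$Y)
  list(Y = X2 + ff$Y, n1 = n1, sa = sa, n2 = n2, ca = ca, n3 = n3, ff = ff)
}
.dec_block_bwd <- function(dY, cache, p) {
  fb <- .ffn_bwd(dY, cache$ff, p$ffn)
  n3b <- .ln_bwd(fb$dX, cache$n3, p$ln3$g)
  dX2 <- dY + n3b$dX
  cb <- .mha_bwd(dX2, cache$ca, p$cross)
  n2b <- .ln_bwd(cb$dXq, cache$n2, p$ln2$g)
  dX1 <- dX2 + n2b$dX
  sb <- .mha_bwd(dX1, cache$sa, p$self)
  n1b <- .ln_bwd(sb$dXq + sb$dXkv, cache$n1, p$ln1$g)
  list(dX = dX1 + n1b$dX, dM = cb$dXkv,
       grads = list(ln1 = list(g = n1b$dg, b = n1b$db), self = sb$grads,
                    ln2 = list(g = n2b$dg, b = n2b$db), cross = cb$grads,
                    ln3 = list(g = n3b$dg, b = n3b$db), ffn = fb$grads))
}

# Masked softmax cross-entropy. `targets` are 0-based ids with NA at masked
# positions (formula prefix, padding). Returns mean loss over unmasked
# positions and the logit gradient.
.ce_fwd_bwd <- function(logits, targets, want_grad = TRUE, smooth = 0) {
  keep <- which(!is.na(targets))
  if (!length(keep)) stop("cross-entropy: no unmasked positions")
  V <- ncol(logits)
  L <- logits[keep, , drop = FALSE]
  L <- L - apply(L, 1L, max)
  logZ <- log(rowSums(exp(L)))
  logP <- L - logZ
  ids <- targets[keep] + 1L
  pick <- cbind(seq_along(keep), ids)
  if (smooth > 0) {
    # label-smoothed target distribution (1-s)*onehot + s/V
    loss <- -mean((1 - smooth) * logP[pick] + smooth * rowMeans(logP))
  } else {
    loss <- -mean(logP[pick])
  }
  if (!want_grad) return(list(loss = loss, dlogits = NULL))
  G <- exp(logP)
  G[pick] <- G[pick] - (1 - smooth)
  if (smooth > 0) G <- G - smooth / V
  G <- G / length(keep)
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[keep, ] <- G
  list(loss = loss, dlogits = dlogits)
}

# -- parameter-tree utilities -------------------------------------------------

# Walk two parallel trees of numeric leaves, applying f leaf-wise.
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- .tree_map2(f, a[[k]], b[[k]])
    out
  } else f(a, b)
}

.tree_zero_like <- function(a) {
  if (is.list(a)) lapply(a, .tree_zero_like) else a * 0
}

.tree_add <- function(a, b) .tree_map2(`+`, a, b)

# Flatten a tree's numeric leaves into one vector (and back), preserving order.
.tree_unlist <- function(a) {
  if (is.list(a)) unlist(lapply(a, .tree_unlist), use.names = FALSE) else as.numeric(a)
}
.tree_relist <- function(a, values, offset = 0L) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) {
      r <- .tree_relist(a[[k]], values, offset)
      out[[k]] <- r$node
      offset <- r$offset
    }
    list(node = out, offset = offset)
  } else {
    nv <- length(a)
    node <- a
    node[] <- values[(offset + 1L):(offset + nv)]
    list(node = node, offset = offset + nv)
  }
}
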