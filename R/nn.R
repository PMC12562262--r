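# Batched forward / backward passes and the Adam optimizer.
#
# Tokens of a batch of B images are stacked into a single (B * (Np + 1)) x D
# matrix so every linear layer, LayerNorm and MLP runs as one BLAS call; only
# the attention softmax is computed per image (and per head), since queries
# must not attend across images. The modular single-sequence operations in
# vit.R define the semantics; tests assert that this batched path reproduces
# them image by image.

# row bookkeeping for one branch at batch size B
seq_layout <- function(Np, B) {
  P1 <- Np + 1L
  list(
    P1 = P1,
    class_rows = (seq_len(B) - 1L) * P1 + 1L,
    patch_rows = as.vector(outer(1L + seq_len(Np), (seq_len(B) - 1L) * P1, `+`)),
    pos_idx = rep(seq_len(P1), times = B),
    gap_group = rep(seq_len(B), each = Np)
  )
}

# stack patchified images for both branches: image b occupies rows
# (b-1)*Np + 1 .. b*Np of each matrix
precompute_patches <- function(images, cfg) {
  stack <- function(P) do.call(rbind, lapply(images, patchify, patch_size = P))
  list(Xs = stack(cfg$branch_small$patch_size),
       Xl = stack(cfg$branch_large$patch_size),
       B = length(images))
}

# column-broadcast helpers; rep(v, each = nrow) recycles at C level and is
# much cheaper than sweep() (which transposes via aperm)
scale_cols <- function(x, g) x * rep(g, each = nrow(x))
add_bias <- function(x, b) x + rep(b, each = nrow(x))

ln_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  iv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * iv
  list(y = add_bias(scale_cols(xhat, g), b), xhat = xhat, iv = iv)
}

ln_bwd <- function(dy, g, cache) {
  dxhat <- scale_cols(dy, g)
  xhat <- cache$xhat
  dx <- cache$iv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# sigmoid-approximate GELU (x * sigmoid(1.702 x)) with the sigmoid cached
# for the backward pass; one exp call keeps the MLP cheap
gelu_fwd <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  list(y = x * s, th = s)
}

gelu_bwd_factor <- function(x, s) {
  s * (1 + 1.702 * x * (1 - s))
}

# forward through one branch; returns pooled features (B x D) and caches
branch_forward <- function(br, bcfg, Xp, B, cache = FALSE) {
  D <- bcfg$embed_dim; Np <- bcfg$n_patches
  lay <- seq_layout(Np, B)
  Z <- matrix(0, B * lay$P1, D)
  Z[lay$class_rows, ] <- matrix(br$cls, B, D, byrow = TRUE)
  Z[lay$patch_rows, ] <- Xp %*% br$E
  Z <- Z + br$pos[lay$pos_idx, , drop = FALSE]

  heads <- bcfg$heads; ds <- bcfg$head_dim
  scl <- 1 / sqrt(ds)
  caches <- if (cache) vector("list", bcfg$depth)
  for (li in seq_along(br$blocks)) {
    p <- br$blocks[[li]]
    c1 <- ln_fwd(Z, p$ln1_g, p$ln1_b)
    Q <- add_bias(c1$y %*% p$Wq, p$bq)
    K <- add_bias(c1$y %*% p$Wk, p$bk)
    V <- add_bias(c1$y %*% p$Wv, p$bv)
    Hc <- matrix(0, nrow(Z), D)
    Amats <- if (cache) vector("list", B * heads)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * lay$P1 + seq_len(lay$P1)
      Qb <- Q[rows, , drop = FALSE]
      Kb <- K[rows, , drop = FALSE]
      Vb <- V[rows, , drop = FALSE]
      for (h in seq_len(heads)) {
        cols <- (h - 1L) * ds + seq_len(ds)
        A <- softmax_rows(tcrossprod(Qb[, cols, drop = FALSE],
                                     Kb[, cols, drop = FALSE]) * scl)
        Hc[rows, cols] <- A %*% Vb[, cols, drop = FALSE]
        if (cache) Amats[[(b - 1L) * heads + h]] <- A
      }
    }
    M <- add_bias(Hc %*% p$Wo, p$bo)
    Zp <- Z + M
    c2 <- ln_fwd(Zp, p$ln2_g, p$ln2_b)
    Hpre <- add_bias(c2$y %*% p$Wm1, p$bm1)
    gf <- gelu_fwd(Hpre)
    Hact <- gf$y
    Zout <- Zp + add_bias(Hact %*% p$Wm2, p$bm2)
    if (cache) {
      caches[[li]] <- list(c1 = c1, Q = Q, K = K, V = V, Hc = Hc, A = Amats,
                           Zp = Zp, c2 = c2, Hpre = Hpre, th = gf$th,
                           Hact = Hact)
    }
    Z <- Zout
  }
  f <- rowsum(Z[lay$patch_rows, , drop = FALSE], lay$gap_group) / Np
  dimnames(f) <- NULL
  list(f = f, Z = Z, caches = caches, lay = lay)
}

# backward through one branch given df (B x D grad of pooled features);
# returns gradients in the same nested structure as the branch parameters
branch_backward <- function(br, bcfg, Xp, B, fwd, df) {
  D <- bcfg$embed_dim; Np <- bcfg$n_patches
  lay <- fwd$lay
  heads <- bcfg$heads; ds <- bcfg$head_dim
  scl <- 1 / sqrt(ds)

  dZ <- matrix(0, B * lay$P1, D)
  dZ[lay$patch_rows, ] <- df[lay$gap_group, , drop = FALSE] / Np

  g <- list(blocks = vector("list", bcfg$depth))
  for (li in rev(seq_along(br$blocks))) {
    p <- br$blocks[[li]]
    ca <- fwd$caches[[li]]
    # MLP sub-layer
    dHact <- dZ %*% t(p$Wm2)
    dWm2 <- crossprod(ca$Hact, dZ)
    dbm2 <- colSums(dZ)
    dHpre <- dHact * gelu_bwd_factor(ca$Hpre, ca$th)
    N2 <- add_bias(scale_cols(ca$c2$xhat, p$ln2_g), p$ln2_b)
    dWm1 <- crossprod(N2, dHpre)
    dbm1 <- colSums(dHpre)
    l2 <- ln_bwd(dHpre %*% t(p$Wm1), p$ln2_g, ca$c2)
    dZp <- dZ + l2$dx
    # attention sub-layer
    dHc <- dZp %*% t(p$Wo)
    dWo <- crossprod(ca$Hc, dZp)
    dbo <- colSums(dZp)
    dQ <- matrix(0, nrow(dZ), D)
    dK <- matrix(0, nrow(dZ), D)
    dV <- matrix(0, nrow(dZ), D)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * lay$P1 + seq_len(lay$P1)
      Qb <- ca$Q[rows, , drop = FALSE]
      Kb <- ca$K[rows, , drop = FALSE]
      Vb <- ca$V[rows, , drop = FALSE]
      dHb <- dHc[rows, , drop = FALSE]
      for (h in seq_len(heads)) {
        cols <- (h - 1L) * ds + seq_len(ds)
        Qh <- Qb[, cols, drop = FALSE]
        Kh <- Kb[, cols, drop = FALSE]
        A <- ca$A[[(b - 1L) * heads + h]]
        dh <- dHb[, cols, drop = FALSE]
        dA <- tcrossprod(dh, Vb[, cols, drop = FALSE])
        dV[rows, cols] <- crossprod(A, dh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- dS %*% Kh * scl
        dK[rows, cols] <- crossprod(dS, Qh) * scl
      }
    }
    N1 <- add_bias(scale_cols(ca$c1$xhat, p$ln1_g), p$ln1_b)
    dWq <- crossprod(N1, dQ); dbq <- colSums(dQ)
    dWk <- crossprod(N1, dK); dbk <- colSums(dK)
    dWv <- crossprod(N1, dV); dbv <- colSums(dV)
    dN1 <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    l1 <- ln_bwd(dN1, p$ln1_g, ca$c1)
    dZ <- dZp + l1$dx
    g$blocks[[li]] <- list(ln1_g = l1$dg, ln1_b = l1$db,
                           Wq = dWq, bq = dbq, Wk = dWk, bk = dbk,
                           Wv = dWv, bv = dbv, Wo = dWo, bo = dbo,
                           ln2_g = l2$dg, ln2_b = l2$db,
                           Wm1 = dWm1, bm1 = dbm1, Wm2 = dWm2, bm2 = dbm2)
  }
  g$E <- crossprod(Xp, dZ[lay$patch_rows, , drop = FALSE])
  g$cls <- matrix(colSums(dZ[lay$class_rows, , drop = FALSE]), 1)
  g$pos <- rowsum(dZ, lay$pos_idx)
  g[c("E", "cls", "pos", "blocks")]
}

# full model forward on a precomputed patch stack
nn_forward <- function(params, cfg, patches, cache = FALSE) {
  B <- patches$B
  fs <- branch_forward(params$s, cfg$branch_small, patches$Xs, B, cache)
  fl <- branch_forward(params$l, cfg$branch_large, patches$Xl, B, cache)
  D <- cfg$branch_small$embed_dim

  mode <- cfg$fusion_mode
  if (mode == "attention") {
    Ws <- softmax_rows(scale_cols(fs$f, params$fus$k))
    Wl <- softmax_rows(scale_cols(fl$f, params$fus$k))
    fused <- Ws * fs$f + Wl * fl$f
    fus_cache <- list(Ws = Ws, Wl = Wl)
  } else {
    fused <- switch(mode,
      average = (fs$f + fl$f) / 2,
      min = pmin(fs$f, fl$f),
      max = pmax(fs$f, fl$f),
      concat = cbind(fs$f, fl$f)
    )
    fus_cache <- NULL
  }
  hp <- params$head
  A1 <- pmax(add_bias(fused %*% hp$W1, hp$b1), 0)
  A2 <- pmax(add_bias(A1 %*% hp$W2, hp$b2), 0)
  logits <- add_bias(A2 %*% hp$W3, hp$b3)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits)
  if (cache) {
    out$cache <- list(fs = fs, fl = fl, fused = fused, A1 = A1, A2 = A2,
                      fus = fus_cache)
  }
  out
}

# full model backward; dlogits is the B x n_classes upstream gradient
nn_backward <- function(params, cfg, patches, fwd, dlogits) {
  ca <- fwd$cache
  hp <- params$head
  g <- list()
  dA2 <- dlogits %*% t(hp$W3)
  g$head <- list(W3 = crossprod(ca$A2, dlogits), b3 = colSums(dlogits))
  dA2 <- dA2 * (ca$A2 > 0)
  g$head$W2 <- crossprod(ca$A1, dA2); g$head$b2 <- colSums(dA2)
  dA1 <- dA2 %*% t(hp$W2)
  dA1 <- dA1 * (ca$A1 > 0)
  g$head$W1 <- crossprod(ca$fused, dA1); g$head$b1 <- colSums(dA1)
  g$head <- g$head[names(hp)]
  dfused <- dA1 %*% t(hp$W1)

  D <- cfg$branch_small$embed_dim
  mode <- cfg$fusion_mode
  if (mode == "attention") {
    k <- params$fus$k
    Ws <- ca$fus$Ws; Wl <- ca$fus$Wl
    fsf <- ca$fs$f; flf <- ca$fl$f
    dWs <- dfused * fsf
    dSs <- Ws * (dWs - rowSums(dWs * Ws))
    dfs <- dfused * Ws + scale_cols(dSs, k)
    dWl <- dfused * flf
    dSl <- Wl * (dWl - rowSums(dWl * Wl))
    dfl <- dfused * Wl + scale_cols(dSl, k)
    g$fus <- list(k = colSums(dSs * fsf) + colSums(dSl * flf))
  } else if (mode == "average") {
    dfs <- dfused / 2; dfl <- dfused / 2
  } else if (mode == "min") {
    m <- ca$fs$f <= ca$fl$f
    dfs <- dfused * m; dfl <- dfused * (!m)
  } else if (mode == "max") {
    m <- ca$fs$f >= ca$fl$f
    dfs <- dfused * m; dfl <- dfused * (!m)
  } else {                                 # concat
    dfs <- dfused[, seq_len(D), drop = FALSE]
    dfl <- dfused[, D + seq_len(D), drop = FALSE]
  }

  g$s <- branch_backward(params$s, cfg$branch_small, patches$Xs, patches$B,
                         ca$fs, dfs)
  g$l <- branch_backward(params$l, cfg$branch_large, patches$Xl, patches$B,
                         ca$fl, dfl)
  g[names(params)]
}

# cross-entropy loss and the softmax+CE gradient; Y is a B x n_classes
# one-hot matrix, w an optional per-sample weight vector
ce_loss_grad <- function(probs, Y, w = NULL) {
  B <- nrow(Y)
  if (is.null(w)) w <- rep(1, B)
  wn <- w / sum(w)
  p_true <- rowSums(probs * Y)
  loss <- -sum(wn * log(pmax(p_true, 1e-12)))
  dlogits <- (probs - Y) * wn
  list(loss = loss, dlogits = dlogits)
}

# ---- Adam ------------------------------------------------------------------

# apply f(p, g, m, v) -> list(p, m, v) over matching nested lists of arrays
tree_walk <- function(p, g, m, v, f) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (nm in names(p)) {
      r <- tree_walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], f)
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  } else {
    f(p, g, m, v)
  }
}

tree_zero <- function(p) {
  if (is.list(p)) lapply(p, tree_zero) else p * 0
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.008,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  r <- tree_walk(params, grads, state$m, state$v, function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  })
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}
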