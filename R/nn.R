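# Numerical core: layer normalization, GELU, multi-head self-attention and
# the pre-LN encoder block, each with a hand-derived backward pass. Token
# matrices are M x d_model (row = token). `valid` marks real (non-padding)
# tokens: padded keys are excluded from the attention softmax so they
# contribute neither to outputs nor to gradients of real tokens.

# Small enough that layer norm is affine-invariant to ~1e-6 even for
# down-scaled inputs; double precision keeps this stable.
.ln_eps <- 1e-8

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + .ln_eps)
  Xhat <- Xc * inv                       # row-wise scaling (column recycling)
  Y <- sweep(sweep(Xhat, 2L, g, `*`), 2L, b, `+`)
  list(Y = Y, Xhat = Xhat, inv = inv, g = g)
}

ln_bwd <- function(dY, cache) {
  dXhat <- sweep(dY, 2L, cache$g, `*`)
  dg <- colSums(dY * cache$Xhat)
  db <- colSums(dY)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * cache$Xhat)
  dX <- cache$inv * (dXhat - m1 - cache$Xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(S) {
  mx <- apply(S, 1L, max)
  E <- exp(S - mx)
  E[is.na(E)] <- 0                      # rows that were all -Inf
  E / pmax(rowSums(E), .Machine$double.xmin)
}

drop_mask <- function(dim1, dim2, p) {
  matrix(stats::rbinom(dim1 * dim2, 1L, 1 - p), dim1, dim2) / (1 - p)
}

mhsa_fwd <- function(Xin, p, nh, p_drop = 0, training = FALSE, valid = NULL,
                     collect_attention = FALSE) {
  M <- nrow(Xin); d <- ncol(Xin); dk <- d %/% nh
  Q <- sweep(Xin %*% t(p$Wq), 2L, p$bq, `+`)
  K <- sweep(Xin %*% t(p$Wk), 2L, p$bk, `+`)
  V <- sweep(Xin %*% t(p$Wv), 2L, p$bv, `+`)
  O <- matrix(0, M, d)
  heads <- vector("list", nh)
  attn <- if (collect_attention) matrix(0, M, M) else NULL
  for (h in seq_len(nh)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- Q[, idx, drop = FALSE]; Kh <- K[, idx, drop = FALSE]
    Vh <- V[, idx, drop = FALSE]
    S <- (Qh %*% t(Kh)) / sqrt(dk)
    if (!is.null(valid) && !all(valid)) S[, !valid] <- -Inf
    A <- softmax_rows(S)
    if (collect_attention) attn <- attn + A / nh
    amask <- if (training && p_drop > 0) drop_mask(M, M, p_drop) else NULL
    Ad <- if (is.null(amask)) A else A * amask
    O[, idx] <- Ad %*% Vh
    heads[[h]] <- list(idx = idx, Qh = Qh, Kh = Kh, Vh = Vh, A = A, Ad = Ad,
                       amask = amask)
  }
  out <- sweep(O %*% t(p$Wo), 2L, p$bo, `+`)
  list(out = out, cache = list(Xin = Xin, O = O, heads = heads, p = p,
                               nh = nh, dk = dk),
       attn = attn)
}

mhsa_bwd <- function(dOut, cache) {
  p <- cache$p; Xin <- cache$Xin; dk <- cache$dk
  dWo <- t(dOut) %*% cache$O
  dbo <- colSums(dOut)
  dO <- dOut %*% p$Wo
  dQ <- matrix(0, nrow(Xin), ncol(Xin))
  dK <- dQ; dV <- dQ
  for (hd in cache$heads) {
    idx <- hd$idx
    dOh <- dO[, idx, drop = FALSE]
    dAd <- dOh %*% t(hd$Vh)
    dVh <- t(hd$Ad) %*% dOh
    dA <- if (is.null(hd$amask)) dAd else dAd * hd$amask
    dS <- hd$A * (dA - rowSums(dA * hd$A))
    dQ[, idx] <- (dS %*% hd$Kh) / sqrt(dk)
    dK[, idx] <- (t(dS) %*% hd$Qh) / sqrt(dk)
    dV[, idx] <- dVh
  }
  dX <- dQ %*% p$Wq + dK %*% p$Wk + dV %*% p$Wv
  list(dX = dX,
       grads = list(Wq = t(dQ) %*% Xin, bq = colSums(dQ),
                    Wk = t(dK) %*% Xin, bk = colSums(dK),
                    Wv = t(dV) %*% Xin, bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

block_param_names <- c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk", "Wv", "bv",
                       "Wo", "bo", "ln2_g", "ln2_b", "W1", "b1", "W2", "b2")

block_fwd <- function(X, bp, nh, p_drop = 0, training = FALSE, valid = NULL,
                      collect_attention = FALSE) {
  l1 <- ln_fwd(X, bp$ln1_g, bp$ln1_b)
  att <- mhsa_fwd(l1$Y, bp, nh, p_drop, training, valid, collect_attention)
  Y <- X + att$out
  l2 <- ln_fwd(Y, bp$ln2_g, bp$ln2_b)
  U <- sweep(l2$Y %*% t(bp$W1), 2L, bp$b1, `+`)
  G <- gelu(U)
  Fo <- sweep(G %*% t(bp$W2), 2L, bp$b2, `+`)
  ffn_mask <- if (training && p_drop > 0) drop_mask(nrow(Fo), ncol(Fo), p_drop)
              else NULL
  Fd <- if (is.null(ffn_mask)) Fo else Fo * ffn_mask
  list(Y = Y + Fd,
       cache = list(l1 = l1, att = att$cache, l2 = l2, U = U, G = G,
                    ffn_mask = ffn_mask, bp = bp),
       attn = att$attn)
}

block_bwd <- function(dZ, cache) {
  bp <- cache$bp
  dFo <- if (is.null(cache$ffn_mask)) dZ else dZ * cache$ffn_mask
  dW2 <- t(dFo) %*% cache$G
  db2 <- colSums(dFo)
  dG <- dFo %*% bp$W2
  dU <- dG * gelu_grad(cache$U)
  dW1 <- t(dU) %*% cache$l2$Y
  db1 <- colSums(dU)
  dl2Y <- dU %*% bp$W1
  l2b <- ln_bwd(dl2Y, cache$l2)
  dY <- dZ + l2b$dX
  ab <- mhsa_bwd(dY, cache$att)
  l1b <- ln_bwd(ab$dX, cache$l1)
  dX <- dY + l1b$dX
  grads <- c(list(ln1_g = l1b$dg, ln1_b = l1b$db,
                  ln2_g = l2b$dg, ln2_b = l2b$db,
                  W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
             ab$grads)
  list(dX = dX, grads = grads[block_param_names])
}

# Full encoder stack plus final layer norm.
encoder_fwd <- function(X0, params, config, training = FALSE, valid = NULL,
                        collect_attention = FALSE) {
  caches <- vector("list", config$n_blocks)
  attn <- if (collect_attention) vector("list", config$n_blocks) else NULL
  X <- X0
  for (b in seq_len(config$n_blocks)) {
    bp <- lapply(block_param_names, function(nm)
      params[[paste0("blk", b, "_", nm)]])
    names(bp) <- block_param_names
    r <- block_fwd(X, bp, config$n_heads, config$p_drop, training, valid,
                   collect_attention)
    caches[[b]] <- r$cache
    if (collect_attention) attn[[b]] <- r$attn
    X <- r$Y
  }
  lf <- ln_fwd(X, params$lnf_g, params$lnf_b)
  list(out = lf$Y, caches = caches, lnf = lf, attn = attn)
}

encoder_bwd <- function(dOut, fwd, config) {
  grads <- list()
  lfb <- ln_bwd(dOut, fwd$lnf)
  grads$lnf_g <- lfb$dg
  grads$lnf_b <- lfb$db
  dX <- lfb$dX
  for (b in rev(seq_len(config$n_blocks))) {
    r <- block_bwd(dX, fwd$caches[[b]])
    names(r$grads) <- paste0("blk", b, "_", names(r$grads))
    grads <- c(grads, r$grads)
    dX <- r$dX
  }
  list(dX0 = dX, grads = grads)
}

# Element-wise accumulate two named gradient lists.
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
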