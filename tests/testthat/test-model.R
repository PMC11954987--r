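test_that("tokenizer slices channel-major patches and drops the remainder", {
  # reference montage: 22 channels, 512-sample window, 64-sample patches
  x <- matrix(rnorm(22 * 512), 22, dimnames = list(sprintf("E%02d", 1:22), NULL))
  ps <- tokenize(x, 64)
  expect_identical(nrow(ps$patches), 22L * 8L)
  expect_identical(ps$n_slots, 8L)
  expect_identical(ps$channel[1:8], rep("E01", 8))

  one <- matrix(rnorm(64), 1, dimnames = list("C3", NULL))
  ps1 <- tokenize(one, 64)
  expect_identical(nrow(ps1$patches), 1L)
  expect_equal(ps1$patches[1, ], one[1, ])

  expect_error(tokenize(one[, 1:30, drop = FALSE], 64), "shorter")
})

test_that("tokenizer agrees with a brute-force slicing oracle", {
  set.seed(10)
  for (rep in 1:12) {
    C <- sample(1:6, 1); D <- sample(3:17, 1)
    T_w <- D + sample(0:80, 1)
    chn <- sprintf("CH%d", seq_len(C))
    x <- matrix(rnorm(C * T_w), C, dimnames = list(chn, NULL))
    ps <- tokenize(x, D)
    S <- T_w %/% D
    expect_identical(nrow(ps$patches), C * S)
    k <- 0L
    for (c in seq_len(C)) for (s in seq_len(S)) {
      k <- k + 1L
      expect_equal(ps$patches[k, ], x[c, ((s - 1) * D + 1):(s * D)])
      expect_identical(ps$channel[k], chn[c])
      expect_identical(ps$slot[k], s)
    }
  }
  # C = 3, T = 130, D = 64: samples 129, 130 of each channel are discarded
  x <- matrix(seq_len(3 * 130), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), NULL))
  ps <- tokenize(x, 64)
  expect_identical(nrow(ps$patches), 6L)
  expect_false(any(c(x[, 129], x[, 130]) %in% ps$patches))
})

test_that("patch embedding is a pure linear map", {
  set.seed(11)
  W <- matrix(rnorm(16 * 8), 16, 8)
  P <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(embed_patches(P, matrix(0, 16, 8)), matrix(0, 5, 16))
  expect_equal(embed_patches(3 * P, W), 3 * embed_patches(P, W))
  onehot <- rbind(replace(numeric(8), 3, 1))
  expect_equal(drop(embed_patches(onehot, W)), W[, 3])
})

test_that("token assembly adds cls and the right positional rows", {
  m <- tiny_model(n_slots = 2L)
  d <- m$config$d_model
  m$params$cls[] <- 0
  m$params$pos[] <- 0
  emb <- matrix(rnorm(4 * d), 4)
  tok <- assemble_tokens(emb, c("C3", "C3", "C4", "C4"), c(1, 2, 1, 2),
                         m$params)
  expect_equal(tok[-1, ], emb)
  expect_equal(tok[1, ], numeric(d))
  # hand-computed 2-patch toy with integer embeddings and positions
  m$params$pos["CLS", ] <- 1
  m$params$pos["C3@1", ] <- 2
  m$params$pos["C4@2", ] <- 10
  m$params$cls[] <- 5
  emb2 <- rbind(rep(1, d), rep(3, d))
  tok2 <- assemble_tokens(emb2, c("C3", "C4"), c(1, 2), m$params)
  expect_equal(rowSums(tok2), c(6, 3, 13) * d)
  # permuting patches together with provenance permutes rows
  tok2p <- assemble_tokens(emb2[2:1, ], c("C4", "C3"), c(2, 1), m$params)
  expect_equal(tok2p[c(1, 3, 2), ], tok2)
  expect_error(assemble_tokens(emb2, c("C3", "FZ"), c(1, 1), m$params),
               "FZ@1")
})

test_that("encoder block has pre-LN residual structure", {
  set.seed(12)
  m <- tiny_model(n_blocks = 1L)
  d <- m$config$d_model
  X <- matrix(rnorm(5 * d), 5)
  bp <- lapply(eegpatch:::block_param_names,
               function(nm) m$params[[paste0("blk1_", nm)]])
  names(bp) <- eegpatch:::block_param_names
  # zero attention output projection + zero second FFN layer: identity map
  bp0 <- bp
  bp0$Wo[] <- 0; bp0$bo[] <- 0; bp0$W2[] <- 0; bp0$b2[] <- 0
  out0 <- eegpatch:::block_fwd(X, bp0, 2L)$Y
  expect_equal(out0, X, tolerance = 1e-12)
  # attention weights are row-stochastic
  r <- eegpatch:::mhsa_fwd(X, bp, 2L)
  for (hd in r$cache$heads)
    expect_equal(rowSums(hd$A), rep(1, 5), tolerance = 1e-6)
})

test_that("encoder block matches a naive dense-attention oracle", {
  set.seed(13)
  D <- 6L
  cfg <- eegpatch_config(D = D, n_blocks = 1L, n_heads = 1L,
                         ffn_hidden = 10L, p_drop = 0, n_classes = 2L)
  m <- init_model(cfg, "C3", n_slots = 3L, seed = 3L)
  d <- cfg$d_model
  X <- matrix(rnorm(3 * d) * 0.7, 3)
  bp <- lapply(eegpatch:::block_param_names,
               function(nm) m$params[[paste0("blk1_", nm)]])
  names(bp) <- eegpatch:::block_param_names
  got <- eegpatch:::block_fwd(X, bp, 1L)$Y
  # independent step-by-step oracle
  H <- naive_layer_norm(X, bp$ln1_g, bp$ln1_b)
  Y <- X + naive_attention(H, bp$Wq, bp$bq, bp$Wk, bp$bk, bp$Wv, bp$bv,
                           bp$Wo, bp$bo)
  H2 <- naive_layer_norm(Y, bp$ln2_g, bp$ln2_b)
  U <- sweep(H2 %*% t(bp$W1), 2, bp$b1, `+`)
  G <- U * pnorm(U)
  want <- Y + sweep(G %*% t(bp$W2), 2, bp$b2, `+`)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("layer norm is invariant to per-token affine shifts a*v + c", {
  set.seed(14)
  g <- rnorm(16); b <- rnorm(16)
  v <- matrix(rnorm(16), 1)
  base <- eegpatch:::ln_fwd(v, g, b)$Y
  for (a in c(0.5, 3, 100)) for (cc in c(-4, 0, 2.5)) {
    y <- eegpatch:::ln_fwd(a * v + cc, g, b)$Y
    expect_lt(max(abs(y - base)), 1e-6)
  }
})

test_that("classification head reads only the cls token and sums to 1", {
  set.seed(15)
  tok <- matrix(rnorm(5 * 12), 5)
  W <- matrix(0, 3, 12); b <- numeric(3)
  expect_equal(classify_tokens(tok, W, b), rep(1 / 3, 3))
  W <- matrix(rnorm(36), 3)
  p1 <- classify_tokens(tok, W, b)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_equal(classify_tokens(tok, W, b + 7), p1, tolerance = 1e-12)
  # closed-form softmax: logits (ln 3, 0) -> (0.75, 0.25)
  tok1 <- rbind(c(1, 0), c(9, 9))
  W2 <- rbind(c(log(3), 0), c(0, 0))
  expect_equal(classify_tokens(tok1, W2, numeric(2)), c(0.75, 0.25))
  # non-cls rows are ignored
  tok_alt <- tok; tok_alt[-1, ] <- rnorm(4 * 12)
  expect_identical(classify_tokens(tok_alt, W, b), p1)
})

test_that("reconstruction head maps every non-cls token to a D-patch", {
  set.seed(16)
  tok <- matrix(rnorm(4 * 10), 4)
  Wr <- matrix(rnorm(6 * 10), 6)
  expect_equal(reconstruct_tokens(tok, matrix(0, 6, 10)), matrix(0, 3, 6))
  got <- reconstruct_tokens(tok, Wr)
  expect_identical(dim(got), c(3L, 6L))
  expect_equal(got[2, ], drop(Wr %*% tok[3, ]))
})

test_that("one state serves montages of different size, deterministically", {
  cfg <- tiny_config()
  m <- init_model(cfg, c("C3", "CZ", "C4", "F3", "F4"), n_slots = 4L,
                  seed = 2L)
  m$classes <- c("A", "B")
  m$augment <- augment_config(crop_window = 32L)
  x3 <- matrix(rnorm(3 * 32), 3, dimnames = list(c("C3", "CZ", "C4"), NULL))
  x5 <- matrix(rnorm(5 * 32), 5,
               dimnames = list(c("C3", "CZ", "C4", "F3", "F4"), NULL))
  p3 <- forward_window(m, x3)
  p5 <- forward_window(m, x5)
  expect_equal(sum(p3), 1, tolerance = 1e-6)
  expect_equal(sum(p5), 1, tolerance = 1e-6)
  expect_identical(forward_window(m, x3), p3)   # eval mode is bit-wise stable
})

test_that("default configuration lands near the reference parameter count", {
  cfg <- eegpatch_config(n_classes = 5L)
  expect_identical(cfg$d_model, 128L)
  expect_identical(cfg$ffn_hidden, 512L)
  m <- init_model(cfg, sprintf("CH%02d", 1:64), n_slots = 8L)
  expect_lt(abs(count_params(m) - 884000) / 884000, 0.10)
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(17)
  cfg <- tiny_config(n_classes = 3L)
  m <- init_model(cfg, c("C3", "C4"), n_slots = 3L, seed = 7L)
  x <- matrix(rnorm(2 * 26), 2, dimnames = list(c("C3", "C4"), NULL))
  ps <- tokenize(x, cfg$D)
  loss_fn <- function(params) {
    emb <- embed_patches(ps$patches, params$W_E)
    tok <- assemble_tokens(emb, ps$channel, ps$slot, params)
    enc <- eegpatch:::encoder_fwd(tok, params, cfg)
    p <- classify_tokens(enc$out, params$W_class, params$b_class)
    -log(p[2])
  }
  st <- eegpatch:::step_supervised(m$params, cfg, ps, 2L, training = FALSE)
  expect_equal(st$loss, loss_fn(m$params), tolerance = 1e-10)
  eps <- 1e-5
  for (nm in c("W_E", "cls", "pos", "W_class", "blk1_Wq", "blk1_ln1_g",
               "blk2_W1", "blk2_bo", "lnf_g")) {
    for (ii in sample(length(m$params[[nm]]), 3L)) {
      pp <- m$params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm <- m$params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      ana <- st$grads[[nm]][ii]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("padded tokens contribute no gradient to real positions", {
  set.seed(18)
  cfg <- tiny_config()
  m <- init_model(cfg, c("C3", "C4"), n_slots = 2L, seed = 5L)
  d <- cfg$d_model
  X <- matrix(rnorm(5 * d), 5)
  Xpad <- rbind(X, matrix(0, 3, d))
  valid <- c(rep(TRUE, 5), rep(FALSE, 3))
  f1 <- eegpatch:::encoder_fwd(X, m$params, cfg)
  f2 <- eegpatch:::encoder_fwd(Xpad, m$params, cfg, valid = valid)
  expect_equal(f2$out[1:5, ], f1$out, tolerance = 1e-10)
  dOut <- matrix(rnorm(5 * d), 5)
  b1 <- eegpatch:::encoder_bwd(dOut, f1, cfg)
  b2 <- eegpatch:::encoder_bwd(rbind(dOut, matrix(0, 3, d)), f2, cfg)
  expect_equal(b2$dX0[1:5, ], b1$dX0, tolerance = 1e-10)
  expect_equal(b2$dX0[6:8, ], matrix(0, 3, d), tolerance = 1e-10)
  for (nm in names(b1$grads))
    expect_equal(b2$grads[[nm]], b1$grads[[nm]], tolerance = 1e-10)
})

test_that("checkpoints round-trip through save_model/load_model", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$params, m$params)
  saveRDS(list(format = "other"), path)
  expect_error(load_model(path), "checkpoint")
})
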