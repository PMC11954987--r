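# Shared fixtures and independent oracles for the test suite.

# Small model configuration used throughout the unit tests.
tiny_config <- function(n_classes = 2L, n_blocks = 2L)
  eegpatch_config(D = 8L, n_blocks = n_blocks, n_heads = 2L,
                  ffn_hidden = 16L, p_drop = 0, n_classes = n_classes)

tiny_model <- function(montage = c("C3", "C4"), n_slots = 3L, seed = 7L,
                       ...) {
  init_model(tiny_config(...), montage, n_slots, seed = seed)
}

random_trial <- function(C = 3, T_len = 1000, fs = 250,
                         channels = c("C3", "CZ", "C4")[seq_len(C)],
                         label = "LEFT_HAND", session = "s01.r01") {
  eeg_trial(matrix(rnorm(C * T_len), C), channels, fs, label = label,
            session_id = session)
}

# Bandpass + per-session z-score, the standard preprocessing chain.
preprocess_sessions <- function(trials, bandpass = FALSE) {
  if (bandpass) trials <- lapply(trials, bandpass_filter)
  sess <- vapply(trials, function(t) t$session_id, character(1))
  unlist(lapply(split(trials, sess), function(ts) session_zscore(ts)$trials),
         recursive = FALSE, use.names = FALSE)
}

# Independent dense single-head attention oracle (naive O(N^2) loops).
naive_attention <- function(X, Wq, bq, Wk, bk, Wv, bv, Wo, bo) {
  N <- nrow(X); d <- ncol(X)
  Q <- X %*% t(Wq); K <- X %*% t(Wk); V <- X %*% t(Wv)
  for (i in seq_len(N)) {
    Q[i, ] <- Q[i, ] + bq; K[i, ] <- K[i, ] + bk; V[i, ] <- V[i, ] + bv
  }
  O <- matrix(0, N, d)
  for (i in seq_len(N)) {
    s <- numeric(N)
    for (j in seq_len(N)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    a <- exp(s - max(s)); a <- a / sum(a)
    for (j in seq_len(N)) O[i, ] <- O[i, ] + a[j] * V[j, ]
  }
  out <- O %*% t(Wo)
  for (i in seq_len(N)) out[i, ] <- out[i, ] + bo
  out
}

# Independent layer-norm oracle (per row, population variance, eps 1e-8).
naive_layer_norm <- function(X, g, b) {
  t(apply(X, 1L, function(r) {
    g * (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-8) + b
  }))
}

# Trial-level periodogram band power (independent of the model code path).
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= lo & f <= hi & f <= fs / 2])
}
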