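#' Model configuration
#'
#' Hyperparameters of the patch-based EEG Transformer. The latent width is
#' tied to the patch length, `d_model = 2 * D`. Defaults reproduce the
#' reference configuration: 64-sample patches (0.256 s at 250 Hz), model
#' width 128, four encoder blocks with hidden size 512 and four attention
#' heads, dropout 0.1 — about 884k parameters on a 64-channel montage.
#'
#' @param D Patch length in samples.
#' @param n_blocks Number of encoder blocks.
#' @param n_heads Attention heads per block (`2 * D` must be divisible by it).
#' @param ffn_hidden Hidden width of the feed-forward sublayer
#'   (default `8 * D`, i.e. four times `d_model`).
#' @param p_drop Dropout rate on attention weights and feed-forward outputs.
#' @param n_classes Number of output classes (set from the data by
#'   [eegpatch()] when `NULL`).
#' @return An object of class `eegpatch_config`.
#' @export
eegpatch_config <- function(D = 64L, n_blocks = 4L, n_heads = 4L,
                            ffn_hidden = 8L * D, p_drop = 0.1,
                            n_classes = NULL) {
  D <- as.integer(D)
  d_model <- 2L * D
  stopifnot(D >= 1L, n_blocks >= 1L, n_heads >= 1L,
            d_model %% n_heads == 0L, p_drop >= 0, p_drop < 1)
  if (!is.null(n_classes) && n_classes < 2L)
    stop("'n_classes' must be at least 2")
  structure(list(D = D, d_model = d_model, n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 ffn_hidden = as.integer(ffn_hidden), p_drop = p_drop,
                 n_classes = if (is.null(n_classes)) NULL else as.integer(n_classes)),
            class = "eegpatch_config")
}

pos_key <- function(channel, slot) paste0(channel, "@", slot)

.init_sd <- 0.02

#' Initialize an untrained model
#'
#' Allocates all parameters for a given montage: the shared patch-embedding
#' matrix, classification token, per-(channel, time-slot) positional
#' embedding registry (one extra row for the classification token), encoder
#' blocks, classification head, patch-reconstruction head and the learned
#' mask token used in self-supervised pre-training. Weights are drawn
#' N(0, 0.02^2); biases and layer-norm offsets start at zero, layer-norm
#' gains at one.
#'
#' @param config An [eegpatch_config()] with `n_classes` set.
#' @param montage Character vector of channel names the positional registry
#'   must cover.
#' @param n_slots Number of time slots per channel in the training window.
#' @param seed Integer seed for the initialization draws.
#' @return An object of class `eegpatch` (untrained: empty training log).
#' @export
init_model <- function(config, montage, n_slots, seed = 1L) {
  stopifnot(inherits(config, "eegpatch_config"))
  if (is.null(config$n_classes)) stop("config$n_classes must be set")
  montage <- toupper(trimws(montage))
  set.seed(as.integer(seed))
  d <- config$d_model; D <- config$D; H <- config$ffn_hidden
  rmat <- function(r, c) matrix(stats::rnorm(r * c, 0, .init_sd), r, c)
  keys <- c("CLS", as.vector(t(outer(montage, seq_len(n_slots), pos_key))))
  params <- list(
    W_E = rmat(d, D),
    cls = rmat(1L, d),
    pos = {
      P <- rmat(length(keys), d); rownames(P) <- keys; P
    },
    mask_token = rmat(1L, d),
    W_class = rmat(config$n_classes, d),
    b_class = numeric(config$n_classes),
    W_recon = rmat(D, d),
    b_recon = numeric(D))
  for (b in seq_len(config$n_blocks)) {
    bp <- list(ln1_g = rep(1, d), ln1_b = numeric(d),
               Wq = rmat(d, d), bq = numeric(d),
               Wk = rmat(d, d), bk = numeric(d),
               Wv = rmat(d, d), bv = numeric(d),
               Wo = rmat(d, d), bo = numeric(d),
               ln2_g = rep(1, d), ln2_b = numeric(d),
               W1 = rmat(H, d), b1 = numeric(H),
               W2 = rmat(d, H), b2 = numeric(d))
    names(bp) <- paste0("blk", b, "_", names(bp))
    params <- c(params, bp)
  }
  params$lnf_g <- rep(1, d)
  params$lnf_b <- numeric(d)
  structure(list(params = params, config = config,
                 montage = montage, n_slots = as.integer(n_slots),
                 classes = NULL, log = NULL, policy = NULL,
                 augment = NULL, objective = NULL, call = NULL),
            class = "eegpatch")
}

#' Count trainable parameters
#'
#' @param object An `eegpatch` model.
#' @return Total number of trainable scalars, including the positional
#'   registry and both heads.
#' @export
count_params <- function(object) {
  sum(vapply(object$params, length, numeric(1)))
}

#' Linear patch embedding
#'
#' Projects patches into the latent space as `X_E = X_P %*% t(W_E)` — a pure
#' linear map with no bias.
#'
#' @param patches N x D patch matrix (or a `patch_seq`).
#' @param W_E d_model x D embedding matrix.
#' @return N x d_model embedding matrix.
#' @export
embed_patches <- function(patches, W_E) {
  if (inherits(patches, "patch_seq")) patches <- patches$patches
  patches %*% t(W_E)
}

#' Prepend the classification token and add positional embeddings
#'
#' Row 0 of the result is the classification token plus its positional
#' vector; row i is the i-th embedded patch plus the positional-registry row
#' for its (channel, time-slot) provenance.
#'
#' @param emb N x d_model embedded patches.
#' @param channel,slot Per-patch provenance (channel label, 1-based slot).
#' @param params Model parameter list holding `cls` and `pos` (an
#'   `eegpatch` object is also accepted).
#' @return (N + 1) x d_model token matrix.
#' @export
assemble_tokens <- function(emb, channel, slot, params) {
  if (inherits(params, "eegpatch")) params <- params$params
  keys <- pos_key(channel, slot)
  missing <- setdiff(unique(keys), rownames(params$pos))
  if (length(missing))
    stop("missing positional embedding for (channel, slot) pair(s): ",
         paste(missing, collapse = ", "),
         " — transfer_weights() grows the registry for a new montage")
  out <- rbind(params$cls[1L, ] + params$pos["CLS", ],
               emb + params$pos[keys, , drop = FALSE])
  dimnames(out) <- NULL
  out
}

#' Classification head
#'
#' Softmax readout of the classification token only:
#' `softmax(cls_token %*% t(W_class) + b_class)`. All other tokens are
#' dropped.
#'
#' @param tokens (N + 1) x d_model encoder output (row 1 = cls token).
#' @param W_class,b_class Head weights (n_classes x d_model) and bias.
#' @return Probability vector over classes (non-negative, sums to 1).
#' @export
classify_tokens <- function(tokens, W_class, b_class) {
  logits <- drop(W_class %*% tokens[1L, ] + b_class)
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Patch reconstruction head
#'
#' Applies the linear reconstruction projection to the non-cls token rows,
#' yielding one D-sample reconstruction per patch.
#'
#' @param tokens (N + 1) x d_model encoder output.
#' @param W_recon,b_recon Projection (D x d_model) and bias.
#' @return N x D matrix of reconstructed patches.
#' @export
reconstruct_tokens <- function(tokens, W_recon, b_recon = numeric(nrow(W_recon))) {
  sweep(tokens[-1L, , drop = FALSE] %*% t(W_recon), 2L, b_recon, `+`)
}

#' Run one window through the model
#'
#' Composition tokenize -> embed -> assemble -> encoder -> head. Works for
#' any channel count whose (channel, slot) pairs are registered in the
#' positional registry; no encoder weight depends on the montage.
#'
#' @param object An `eegpatch` model.
#' @param x Channels x samples window (its length is tokenized as-is), or an
#'   [eeg_trial()].
#' @param channel_names Channel labels when `x` is a bare matrix.
#' @param mode `"classify"` for class probabilities, `"reconstruct"` for
#'   per-patch reconstructions.
#' @param collect_attention Also return per-block head-averaged attention
#'   matrices (evaluation mode).
#' @return Probability vector, or N x D reconstruction matrix; with
#'   `collect_attention = TRUE`, a list with `value`, `attn`, `channel`,
#'   `slot`.
#' @export
forward_window <- function(object, x, channel_names = NULL,
                           mode = c("classify", "reconstruct"),
                           collect_attention = FALSE) {
  mode <- match.arg(mode)
  ps <- tokenize(x, object$config$D, channel_names)
  emb <- embed_patches(ps, object$params$W_E)
  tok <- assemble_tokens(emb, ps$channel, ps$slot, object$params)
  enc <- encoder_fwd(tok, object$params, object$config, training = FALSE,
                     collect_attention = collect_attention)
  value <- if (mode == "classify")
    classify_tokens(enc$out, object$params$W_class, object$params$b_class)
  else
    reconstruct_tokens(enc$out, object$params$W_recon, object$params$b_recon)
  if (collect_attention)
    list(value = value, attn = enc$attn, channel = ps$channel, slot = ps$slot)
  else value
}

#' Save / load a model checkpoint
#'
#' Single-archive checkpoint holding the configuration, every parameter
#' tensor, the positional-registry keys and a format tag.
#'
#' @param object An `eegpatch` model.
#' @param path Checkpoint file path.
#' @return `load_model` returns the restored `eegpatch` object.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "eegpatch"))
  saveRDS(list(format = "eegpatch-checkpoint/1", model = object), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "eegpatch-checkpoint/1"))
    stop("not an eegpatch checkpoint: ", path)
  obj$model
}
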