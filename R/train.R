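#' Optimization policy
#'
#' Hyperparameters of the AdamW training loop: linear learning-rate warm-up
#' from 0 to `lr_max` followed by cosine decay to `lr_min`, decoupled weight
#' decay 0.01 excluding biases, layer-norm parameters, the positional
#' registry, the classification token and (by default) the classification
#' head, betas (0.9, 0.95), and gradient clipping at global norm 1. The
#' schedule is stepped once per optimizer step.
#'
#' @param lr_max,lr_min Peak and final learning rates.
#' @param warmup_epochs,total_epochs Warm-up and total epoch counts (one
#'   epoch = one pass over all training trials).
#' @param weight_decay Decoupled decay for embedding / attention /
#'   feed-forward / reconstruction weights.
#' @param head_weight_decay Decay for the classification head (0 except in
#'   supervised pre-training, where 1 is used because the head is discarded
#'   before fine-tuning).
#' @param betas AdamW (beta1, beta2).
#' @param grad_clip_norm Global gradient-norm clip.
#' @param batch_size Trials per optimizer step.
#' @param rng_seed Seed controlling every source of randomness in a fit.
#' @return An object of class `train_policy`.
#' @export
train_policy <- function(lr_max = 3e-4, lr_min = 3e-5, warmup_epochs = 10L,
                         total_epochs = 100L, weight_decay = 0.01,
                         head_weight_decay = 0, betas = c(0.9, 0.95),
                         grad_clip_norm = 1, batch_size = 32L, rng_seed = 1L) {
  stopifnot(lr_max >= 0, lr_min >= 0, lr_min <= lr_max,
            warmup_epochs >= 0, warmup_epochs <= total_epochs,
            total_epochs >= 1, length(betas) == 2L,
            weight_decay >= 0, head_weight_decay >= 0,
            grad_clip_norm > 0, batch_size >= 1)
  structure(list(lr_max = lr_max, lr_min = lr_min,
                 warmup_epochs = as.integer(warmup_epochs),
                 total_epochs = as.integer(total_epochs),
                 weight_decay = weight_decay,
                 head_weight_decay = head_weight_decay,
                 betas = betas, grad_clip_norm = grad_clip_norm,
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed)),
            class = "train_policy")
}

#' @rdname train_policy
#' @param ... Overrides passed to [train_policy()].
#' @details `pretrain_policy()` is the supervised pre-training variant:
#'   600 epochs with a 100-epoch warm-up and head weight decay 1.
#' @export
pretrain_policy <- function(...) {
  defaults <- list(total_epochs = 600L, warmup_epochs = 100L,
                   head_weight_decay = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_policy, args)
}

#' Learning-rate schedule
#'
#' Linear ramp from 0 at step 0 to `lr_max` at `warmup_steps`, then cosine
#' decay to `lr_min` at `total_steps` (monotone non-increasing after the
#' warm-up). Vectorized over `step`.
#'
#' @param step Optimizer step (0-based).
#' @param warmup_steps,total_steps Schedule breakpoints in steps.
#' @param lr_max,lr_min Peak and final learning rates.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(step, warmup_steps, total_steps,
                        lr_max = 3e-4, lr_min = 3e-5) {
  step <- pmin(step, total_steps)
  ifelse(step < warmup_steps & warmup_steps > 0,
         lr_max * step / warmup_steps,
         {
           denom <- max(total_steps - warmup_steps, 1L)
           frac <- (step - warmup_steps) / denom
           lr_min + (lr_max - lr_min) * 0.5 * (1 + cos(pi * frac))
         })
}

#' Weight-decay parameter groups
#'
#' Assigns every trainable tensor exactly one decay value: `weight_decay`
#' on the embedding, attention, feed-forward and reconstruction weights;
#' zero on all biases, layer-norm parameters, the positional registry, the
#' classification token and the mask token; `head_weight_decay` on the
#' classification head weights.
#'
#' @param object An `eegpatch` model (or its parameter list).
#' @param weight_decay,head_weight_decay Decay values (see [train_policy()]).
#' @return Data frame with one row per parameter tensor: `param`, `decay`,
#'   `group` (`"decay"`, `"no_decay"` or `"head"`).
#' @export
build_param_groups <- function(object, weight_decay = 0.01,
                               head_weight_decay = 0) {
  params <- if (inherits(object, "eegpatch")) object$params else object
  nm <- names(params)
  decay_pat <- "^(W_E|W_recon|blk[0-9]+_(Wq|Wk|Wv|Wo|W1|W2))$"
  group <- ifelse(nm == "W_class", "head",
                  ifelse(grepl(decay_pat, nm), "decay", "no_decay"))
  decay <- ifelse(group == "head", head_weight_decay,
                  ifelse(group == "decay", weight_decay, 0))
  data.frame(param = nm, decay = decay, group = group,
             stringsAsFactors = FALSE)
}

#' Amalgamate dataset-specific labels into the unified class space
#'
#' Supervised pre-training across heterogeneous motor-imagery datasets uses
#' five unified classes: `LEFT_HAND`, `RIGHT_HAND`, `FEET`, `REST`,
#' `BOTH_HANDS`. The default map translates common native spellings
#' ("left hand", "feet"/"foot", "rest", "both hands", ...) irrespective of
#' the dataset; a map may also carry a `dataset_id` column for
#' dataset-specific rows.
#'
#' @param label Native label string.
#' @param dataset_id Dataset identifier (used in error messages and for
#'   dataset-specific map rows).
#' @param map Data frame with columns `native`, `unified` and optionally
#'   `dataset_id`.
#' @return The unified class name.
#' @export
amalgamate <- function(label, dataset_id = "", map = label_map_default()) {
  key <- tolower(trimws(label))
  rows <- map
  if (!is.null(map$dataset_id)) {
    specific <- map[!is.na(map$dataset_id) & map$dataset_id == dataset_id, ]
    generic <- map[is.na(map$dataset_id), ]
    rows <- rbind(specific, generic)
  }
  hit <- match(key, tolower(rows$native))
  if (is.na(hit))
    stop("no unified class for label '", label, "' in dataset '",
         dataset_id, "'")
  rows$unified[hit]
}

#' @rdname amalgamate
#' @export
label_map_default <- function() {
  data.frame(
    native = c("left hand", "left_hand", "right hand", "right_hand",
               "feet", "foot", "rest", "both hands", "both_hands"),
    unified = c("LEFT_HAND", "LEFT_HAND", "RIGHT_HAND", "RIGHT_HAND",
                "FEET", "FEET", "REST", "BOTH_HANDS", "BOTH_HANDS"),
    stringsAsFactors = FALSE)
}

#' Shuffled mixed-dataset batching
#'
#' Partitions trial indices into shuffled batches; every trial appears in
#' exactly one batch per epoch. Batches may mix datasets and channel
#' counts — each trial is tokenized with its own montage, so no architecture
#' change is needed for heterogeneous batches.
#'
#' @param n_trials Number of trials.
#' @param batch_size Batch size.
#' @param shuffle Shuffle before splitting.
#' @return List of integer index vectors.
#' @export
make_mixed_batches <- function(n_trials, batch_size, shuffle = TRUE) {
  idx <- if (shuffle) sample.int(n_trials) else seq_len(n_trials)
  unname(split(idx, ceiling(seq_along(idx) / batch_size)))
}

# ---- gradient machinery ------------------------------------------------

zero_like <- function(params) lapply(params, function(p) p * 0)

global_grad_norm <- function(grads)
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))

clip_grads <- function(grads, max_norm) {
  nrm <- global_grad_norm(grads)
  if (nrm > max_norm) {
    grads <- scale_grads(grads, max_norm / nrm)
    nrm <- global_grad_norm(grads)   # realized norm after rescaling
  }
  list(grads = grads, norm = nrm)
}

adamw_init <- function(params)
  list(m = zero_like(params), v = zero_like(params), t = 0L)

adamw_step <- function(params, grads, opt, lr, decay, betas, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * decay[[nm]] * params[[nm]]
  }
  list(params = params, opt = opt)
}

# ---- per-trial training steps ------------------------------------------

# Supervised step: cross-entropy on the classification token.
step_supervised <- function(params, config, ps, y_index, training = TRUE) {
  emb <- embed_patches(ps$patches, params$W_E)
  keys <- pos_key(ps$channel, ps$slot)
  tok0 <- assemble_tokens(emb, ps$channel, ps$slot, params)
  enc <- encoder_fwd(tok0, params, config, training = training)
  cls_out <- enc$out[1L, ]
  logits <- drop(params$W_class %*% cls_out + params$b_class)
  z <- exp(logits - max(logits)); prob <- z / sum(z)
  loss <- -log(max(prob[y_index], 1e-12))
  dlogits <- prob
  dlogits[y_index] <- dlogits[y_index] - 1
  grads <- list(W_class = outer(dlogits, cls_out), b_class = dlogits)
  dTok <- matrix(0, nrow(enc$out), ncol(enc$out))
  dTok[1L, ] <- drop(t(params$W_class) %*% dlogits)
  bk <- encoder_bwd(dTok, enc, config)
  grads <- c(grads, bk$grads)
  grads <- acc_grads(grads, input_grads(bk$dX0, ps, emb, keys, params,
                                        w_e_rows = seq_len(nrow(emb))))
  list(loss = loss, prob = prob, grads = grads)
}

# Gradients through the embedding path. `w_e_rows` are the patch rows whose
# gradient flows back into W_E (rows replaced during SSL corruption do not).
input_grads <- function(dX0, ps, emb, keys, params, w_e_rows,
                        masked_rows = integer(0)) {
  dcls <- dX0[1L, , drop = FALSE]
  dEmb <- dX0[-1L, , drop = FALSE]
  dpos <- matrix(0, nrow(params$pos), ncol(params$pos),
                 dimnames = dimnames(params$pos))
  dpos["CLS", ] <- dcls
  for (i in seq_along(keys)) dpos[keys[i], ] <- dpos[keys[i], ] + dEmb[i, ]
  g <- list(cls = dcls, pos = dpos)
  if (length(w_e_rows))
    g$W_E <- t(dEmb[w_e_rows, , drop = FALSE]) %*%
      ps$patches[w_e_rows, , drop = FALSE]
  if (length(masked_rows))
    g$mask_token <- matrix(colSums(dEmb[masked_rows, , drop = FALSE]),
                           1L, ncol(dEmb))
  g
}

# Self-supervised step: cosine reconstruction of manipulated patches.
step_ssl <- function(params, config, ps, plan, pool, training = TRUE) {
  emb <- embed_patches(ps$patches, params$W_E)
  cr <- corrupt_tokens(emb, ps$slot, plan, params$mask_token, pool)
  keys <- pos_key(ps$channel, ps$slot)
  tok0 <- assemble_tokens(cr$emb, ps$channel, ps$slot, params)
  enc <- encoder_fwd(tok0, params, config, training = training)
  recons <- reconstruct_tokens(enc$out, params$W_recon, params$b_recon)
  man <- cr$manipulated
  if (!length(man)) return(list(loss = NA_real_, grads = NULL, n = 0L))
  loss <- batch_recon_loss(recons, ps$patches, man)
  dRec <- matrix(0, nrow(recons), ncol(recons))
  for (i in man)
    dRec[i, ] <- recon_loss_grad(recons[i, ], ps$patches[i, ]) / length(man)
  grads <- list(W_recon = t(dRec) %*% enc$out[-1L, , drop = FALSE],
                b_recon = colSums(dRec))
  dTok <- rbind(0, dRec %*% params$W_recon)
  bk <- encoder_bwd(dTok, enc, config)
  grads <- c(grads, bk$grads)
  # W_E gradient flows only through rows that kept their own embedding;
  # mask rows route to the mask token, random rows to nothing (pool is
  # treated as constant).
  w_e_rows <- setdiff(seq_len(nrow(emb)), c(cr$masked_rows, cr$random_rows))
  grads <- acc_grads(grads, input_grads(bk$dX0, ps, emb, keys, params,
                                        w_e_rows = w_e_rows,
                                        masked_rows = cr$masked_rows))
  list(loss = loss, grads = grads, n = length(man))
}
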