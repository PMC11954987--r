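#' Fit a patch-based Transformer to EEG trials
#'
#' The main fitting function. Trials are augmented per epoch (random
#' time-shift cropping and, if enabled, noise / DC-shift / amplitude-scale
#' operators and channel subsampling), tokenized channel-wise into
#' `D`-sample patches, linearly embedded, tagged with learned
#' (channel, time-slot) positional embeddings, and processed by a pre-LN
#' Transformer encoder. With `objective = "supervised"` the classification
#' token is read out through a softmax head trained with cross-entropy;
#' with `objective = "ssl"` time slots are randomly manipulated
#' (mask / random / keep) and the model is trained to reconstruct the
#' original patches under a cosine loss (masked-patch self-supervised
#' pre-training). Optimization is AdamW with decoupled weight decay,
#' per-step warm-up + cosine learning-rate schedule, and global
#' gradient-norm clipping. Everything is reproducible from
#' `policy$rng_seed`.
#'
#' Trials may have heterogeneous montages (mixed datasets): each trial is
#' tokenized with its own channels and the positional registry covers the
#' union of all montages.
#'
#' @param trials List of [eeg_trial()]s (preprocessed: bandpass + session
#'   z-score).
#' @param objective `"supervised"` or `"ssl"`.
#' @param config An [eegpatch_config()]; `n_classes` defaults to the number
#'   of distinct labels.
#' @param policy A [train_policy()].
#' @param augment An [augment_config()].
#' @param init Optional pre-trained `eegpatch` object (e.g. from
#'   [transfer_weights()]) to start from instead of random initialization.
#' @param validation Optional list of held-out trials; accuracy is logged
#'   each epoch.
#' @param label_map Optional label map: when given, trial labels are passed
#'   through [amalgamate()] first.
#' @param verbose Print a line per epoch.
#' @return An object of class `eegpatch` with the fitted parameters, the
#'   configuration, the class levels and a per-epoch training log
#'   (`epoch`, `loss`, `accuracy`, `val_accuracy`, `lr`, `grad_norm`).
#' @seealso [predict.eegpatch()], [transfer_weights()], [synth_generate()]
#' @export
eegpatch <- function(trials, objective = c("supervised", "ssl"),
                     config = eegpatch_config(), policy = train_policy(),
                     augment = augment_config(), init = NULL,
                     validation = NULL, label_map = NULL, verbose = FALSE) {
  objective <- match.arg(objective)
  cl <- match.call()
  stopifnot(length(trials) >= 1L,
            all(vapply(trials, is.eeg_trial, logical(1))))
  D <- config$D
  crop <- augment$crop_window
  min_T <- min(vapply(trials, function(t) ncol(t$signal), numeric(1)))
  if (crop > min_T)
    stop("crop_window (", crop, ") exceeds the shortest trial (", min_T, ")")
  n_slots <- crop %/% D
  if (n_slots < 1L) stop("crop_window shorter than one patch")
  montage <- unique(unlist(lapply(trials, function(t) t$channel_names)))

  classes <- NULL
  y <- NULL
  if (objective == "supervised") {
    labels <- trial_labels(trials)
    if (!is.null(label_map))
      labels <- vapply(seq_along(trials), function(i)
        amalgamate(labels[i], trials[[i]]$dataset_id, label_map),
        character(1))
    if (anyNA(labels)) stop("supervised fitting needs a label on every trial")
    classes <- sort(unique(labels))
    if (length(classes) < 2L) stop("need at least 2 classes")
    if (is.null(config$n_classes)) config$n_classes <- length(classes)
    if (config$n_classes != length(classes))
      stop("config$n_classes (", config$n_classes,
           ") does not match the data (", length(classes), " classes)")
    y <- match(labels, classes)
  }

  if (is.null(init)) {
    if (is.null(config$n_classes))
      config$n_classes <- 2L  # ssl: head unused but allocated
    model <- init_model(config, montage, n_slots, seed = policy$rng_seed)
  } else {
    stopifnot(inherits(init, "eegpatch"))
    model <- init
    config <- model$config
    miss <- setdiff(pos_key(rep(montage, each = n_slots),
                            rep(seq_len(n_slots), length(montage))),
                    rownames(model$params$pos))
    if (length(miss))
      stop("initial model does not cover the data montage (",
           paste(utils::head(miss, 4L), collapse = ", "),
           if (length(miss) > 4L) ", ..." else "",
           "); use transfer_weights() first")
    if (objective == "supervised" && config$n_classes != length(classes))
      stop("initial model has ", config$n_classes, " classes but the data ",
           "has ", length(classes), "; use transfer_weights() to ",
           "reinitialize the head")
  }
  params <- model$params

  set.seed(policy$rng_seed)
  decay_df <- build_param_groups(params, policy$weight_decay,
                                 policy$head_weight_decay)
  decay <- stats::setNames(as.list(decay_df$decay), decay_df$param)
  opt <- adamw_init(params)
  n <- length(trials)
  spe <- ceiling(n / policy$batch_size)
  warmup_steps <- policy$warmup_epochs * spe
  total_steps <- policy$total_epochs * spe
  gstep <- 0L
  log_rows <- vector("list", policy$total_epochs)

  for (epoch in seq_len(policy$total_epochs)) {
    batches <- make_mixed_batches(n, policy$batch_size)
    ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L; ep_gnorm <- 0
    for (batch in batches) {
      # per-trial augmented windows for this step
      wins <- lapply(batch, function(i) {
        tr <- trials[[i]]
        if (augment$channel_keep_prob < 1) tr <- subsample_channels(tr, augment$channel_keep_prob)
        x <- apply_augment(tr$signal, augment, training = TRUE)
        tokenize(x, D, tr$channel_names)
      })
      pool <- if (objective == "ssl")
        do.call(rbind, lapply(wins, function(ps)
          embed_patches(ps$patches, params$W_E)))
      else NULL
      grads <- NULL; used <- 0L
      for (k in seq_along(batch)) {
        ps <- wins[[k]]
        if (objective == "supervised") {
          st <- step_supervised(params, config, ps, y[batch[k]])
          ep_correct <- ep_correct + (which.max(st$prob) == y[batch[k]])
        } else {
          plan <- plan_mask(ps$n_slots)
          st <- step_ssl(params, config, ps, plan, pool)
          if (is.null(st$grads)) next
        }
        grads <- acc_grads(grads, st$grads)
        ep_loss <- ep_loss + st$loss
        used <- used + 1L
      }
      ep_n <- ep_n + used
      if (is.null(grads)) { gstep <- gstep + 1L; next }
      grads <- scale_grads(grads, 1 / used)
      cg <- clip_grads(grads, policy$grad_clip_norm)
      ep_gnorm <- max(ep_gnorm, cg$norm)
      gstep <- gstep + 1L
      lr <- lr_schedule(gstep, warmup_steps, total_steps,
                        policy$lr_max, policy$lr_min)
      upd <- adamw_step(params, cg$grads, opt, lr, decay, policy$betas)
      params <- upd$params
      opt <- upd$opt
    }
    val_acc <- NA_real_
    if (!is.null(validation) && objective == "supervised") {
      model$params <- params
      model$classes <- classes
      model$config <- config
      model$augment <- augment
      pred <- predict(model, validation, type = "class")
      val_labels <- trial_labels(validation)
      if (!is.null(label_map))
        val_labels <- vapply(seq_along(validation), function(i)
          amalgamate(val_labels[i], validation[[i]]$dataset_id, label_map),
          character(1))
      val_acc <- mean(pred == val_labels)
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch,
      loss = ep_loss / max(ep_n, 1L),
      accuracy = if (objective == "supervised") ep_correct / max(ep_n, 1L)
                 else NA_real_,
      val_accuracy = val_acc,
      lr = lr_schedule(gstep, warmup_steps, total_steps,
                       policy$lr_max, policy$lr_min),
      grad_norm = ep_gnorm)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %s  val %s",
                      epoch, log_rows[[epoch]]$loss,
                      format(log_rows[[epoch]]$accuracy, digits = 3),
                      format(val_acc, digits = 3)))
  }

  model$params <- params
  model$config <- config
  model$classes <- classes
  model$montage <- montage
  model$n_slots <- n_slots
  model$policy <- policy
  model$augment <- augment
  model$objective <- objective
  model$log <- do.call(rbind, log_rows)
  model$call <- cl
  model
}

#' Transfer pre-trained weights to a new montage and class count
#'
#' Copies the patch embedding, classification token, encoder blocks, final
#' layer norm, mask token and reconstruction head from a pre-trained model.
#' Positional-registry rows are copied for every (channel, time-slot) key
#' seen in pre-training and freshly initialized for new keys; the
#' classification head is reinitialized for `n_classes`.
#'
#' @param pretrained A fitted `eegpatch` object.
#' @param montage Channel names of the fine-tuning dataset.
#' @param n_classes Number of fine-tuning classes.
#' @param n_slots Time slots per channel (defaults to the pre-training
#'   value).
#' @param seed Seed for the freshly initialized tensors.
#' @return An untrained `eegpatch` object to pass as `init` to [eegpatch()].
#' @export
transfer_weights <- function(pretrained, montage, n_classes,
                             n_slots = pretrained$n_slots, seed = 1L) {
  stopifnot(inherits(pretrained, "eegpatch"))
  montage <- toupper(trimws(montage))
  config <- pretrained$config
  config$n_classes <- as.integer(n_classes)
  fresh <- init_model(config, montage, n_slots, seed = seed)
  keep <- setdiff(names(pretrained$params), c("pos", "W_class", "b_class"))
  for (nm in keep) fresh$params[[nm]] <- pretrained$params[[nm]]
  shared <- intersect(rownames(fresh$params$pos),
                      rownames(pretrained$params$pos))
  fresh$params$pos[shared, ] <- pretrained$params$pos[shared, ]
  fresh$transferred_keys <- setdiff(shared, "CLS")
  fresh
}

#' Predict from a fitted EEG patch Transformer
#'
#' Deterministic evaluation: the window is fixed at the center of each
#' trial, dropout is off, and two calls agree bit-wise.
#'
#' @param object A fitted `eegpatch` model.
#' @param newdata List of [eeg_trial()]s (or a single trial).
#' @param type `"prob"` for the class-probability matrix, `"class"` for
#'   labels.
#' @param ... Unused.
#' @return Matrix (trials x classes) of probabilities, or a character vector
#'   of class labels.
#' @export
predict.eegpatch <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.eeg_trial(newdata)) newdata <- list(newdata)
  crop <- object$augment$crop_window %||% (object$n_slots * object$config$D)
  probs <- t(vapply(newdata, function(tr) {
    x <- augment_time_shift(tr$signal, min(crop, ncol(tr$signal)),
                            center = TRUE)
    forward_window(object, x, tr$channel_names, mode = "classify")
  }, numeric(object$config$n_classes)))
  colnames(probs) <- object$classes
  if (type == "prob") probs
  else {
    cls <- object$classes %||% as.character(seq_len(ncol(probs)))
    cls[max.col(probs)]
  }
}

#' @export
print.eegpatch <- function(x, ...) {
  cat("Patch-based EEG Transformer\n")
  cat(sprintf("  patch D = %d, d_model = %d, %d blocks x %d heads, ffn %d\n",
              x$config$D, x$config$d_model, x$config$n_blocks,
              x$config$n_heads, x$config$ffn_hidden))
  cat(sprintf("  montage: %d channels, %d time slots; parameters: %s\n",
              length(x$montage), x$n_slots,
              format(count_params(x), big.mark = ",")))
  if (!is.null(x$classes))
    cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  if (!is.null(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  trained %d epochs (%s): loss %.4f%s\n",
                nrow(x$log), x$objective %||% "?", last$loss,
                if (!is.na(last$accuracy))
                  sprintf(", train acc %.3f", last$accuracy) else ""))
  } else cat("  (untrained)\n")
  invisible(x)
}

#' @export
summary.eegpatch <- function(object, ...) {
  groups <- build_param_groups(object,
                               object$policy$weight_decay %||% 0.01,
                               object$policy$head_weight_decay %||% 0)
  structure(list(model = object, param_count = count_params(object),
                 groups = table(groups$group)),
            class = "summary.eegpatch")
}

#' @export
print.summary.eegpatch <- function(x, ...) {
  print(x$model)
  cat("  parameter tensors by decay group:\n")
  print(x$groups)
  invisible(x)
}

#' @export
coef.eegpatch <- function(object, ...) object$params

#' Plot training curves
#'
#' @param x A fitted `eegpatch` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eegpatch <- function(x, ...) {
  if (is.null(x$log)) stop("model has no training log")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$log$epoch, x$log$loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training loss", ...)
  if (!all(is.na(x$log$accuracy))) {
    graphics::plot(x$log$epoch, x$log$accuracy, type = "l", ylim = c(0, 1),
                   xlab = "epoch", ylab = "accuracy", main = "accuracy", ...)
    if (!all(is.na(x$log$val_accuracy)))
      graphics::lines(x$log$epoch, x$log$val_accuracy, lty = 2)
  } else {
    graphics::plot(x$log$epoch, x$log$lr, type = "l", xlab = "epoch",
                   ylab = "learning rate", main = "schedule", ...)
  }
  invisible(x)
}
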