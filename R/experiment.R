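#' Augmentation ablation on a fixed evaluation split
#'
#' Reproduces the augmentation-by-data-fraction protocol: a 30% evaluation
#' split is fixed once (class-stratified) and kept identical for every
#' cell; the model is then trained from scratch on 10% / 17.5% / 35% / 70%
#' fractions of the remaining trials (subject-stratified, fixed across
#' regimes) under each augmentation regime — none, Gaussian noise, DC
#' shifts, amplitude scaling, time shifts, and time shifts + noise —
#' reporting top-1 evaluation accuracy per cell and seed.
#'
#' @param trials List of preprocessed [eeg_trial()]s.
#' @param config An [eegpatch_config()].
#' @param policy A [train_policy()]; its `rng_seed` is replaced by each
#'   element of `seeds` in turn.
#' @param crop_window Window length in samples for every regime.
#' @param fractions Training-data fractions of the non-evaluation trials.
#' @param eval_fraction Held-out fraction (default 0.3).
#' @param seeds Training seeds.
#' @param split_seed Seed fixing the evaluation split and the fraction
#'   subsets (shared by all cells).
#' @param verbose Print one line per completed cell.
#' @return Data frame with columns `regime`, `fraction`, `seed`,
#'   `accuracy`, `n_train`; attributes `eval_checksum` (sum of the sorted
#'   evaluation indices, proving the split is shared) and `eval_idx`.
#' @export
ablate_augment <- function(trials, config, policy,
                           crop_window = 512L,
                           fractions = c(0.10, 0.175, 0.35, 0.70),
                           eval_fraction = 0.3, seeds = 1:3,
                           split_seed = 20260101L, verbose = FALSE) {
  labels <- trial_labels(trials)
  subjects <- vapply(trials, function(t) t$subject_id, character(1))
  set.seed(split_seed)
  eval_idx <- sort(unlist(lapply(split(seq_along(trials), labels),
                                 function(ix) sample(ix, max(1L, round(eval_fraction * length(ix)))))))
  train_pool <- setdiff(seq_along(trials), eval_idx)
  # subject-stratified fraction subsets, fixed across regimes and seeds
  frac_idx <- lapply(fractions, function(fr) {
    sort(unlist(lapply(split(train_pool, subjects[train_pool]), function(ix)
      sample(ix, max(1L, round(fr * length(ix)))))))
  })
  regimes <- list(
    none = augment_config(time_shift = FALSE, crop_window = crop_window),
    gaussian_noise = augment_config(noise = TRUE, time_shift = FALSE,
                                    crop_window = crop_window),
    dc_shift = augment_config(dc_shift = TRUE, time_shift = FALSE,
                              crop_window = crop_window),
    amplitude_scaling = augment_config(amplitude_scale = TRUE,
                                       time_shift = FALSE,
                                       crop_window = crop_window),
    time_shift = augment_config(time_shift = TRUE,
                                crop_window = crop_window),
    time_shift_noise = augment_config(time_shift = TRUE, noise = TRUE,
                                      crop_window = crop_window))
  eval_trials <- trials[eval_idx]
  eval_labels <- labels[eval_idx]
  rows <- list()
  for (rg in names(regimes)) {
    for (fi in seq_along(fractions)) {
      for (sd in seeds) {
        pol <- policy
        pol$rng_seed <- as.integer(sd)
        fit <- eegpatch(trials[frac_idx[[fi]]], objective = "supervised",
                        config = config, policy = pol,
                        augment = regimes[[rg]])
        acc <- mean(predict(fit, eval_trials, type = "class") == eval_labels)
        rows[[length(rows) + 1L]] <- data.frame(
          regime = rg, fraction = fractions[fi], seed = sd, accuracy = acc,
          n_train = length(frac_idx[[fi]]))
        if (verbose)
          message(sprintf("%-18s frac %5.3f seed %d  acc %.3f",
                          rg, fractions[fi], sd, acc))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "eval_idx") <- eval_idx
  attr(out, "eval_checksum") <- sum(eval_idx)
  out
}

#' Run a configured experiment
#'
#' Thin experiment runner behind the command-line interface. `spec` is a
#' named list (or the path of a YAML file holding one) with a `mode` and
#' mode-specific fields; every run writes a `manifest.json` (resolved
#' configuration + seed + package version) to `out_dir` sufficient to
#' reproduce it.
#'
#' Modes:
#' \describe{
#'   \item{`synth`}{`synth:` config fields; writes one session file per
#'     subject plus the manifest.}
#'   \item{`train-scratch`, `pretrain-sup`, `pretrain-ssl`}{`sessions:`
#'     session-file paths (or `synth:` inline); optional `model:`,
#'     `policy:`, `augment:` overrides; preprocesses (bandpass + session
#'     z-score, switchable via `preprocess: false`), fits, writes
#'     `log.csv`, `metrics.json` and `model.rds`.}
#'   \item{`finetune`}{as above plus `checkpoint:` of a pre-trained model;
#'     weights are transferred to the new montage/classes first.}
#'   \item{`ablate-augment`}{runs [ablate_augment()]; writes
#'     `ablation.csv`.}
#'   \item{`inspect`}{`checkpoint:` + `sessions:`; writes
#'     `filter_spectra.csv`, `pos_similarity.csv` and a rollout PNG per
#'     inspected trial.}
#' }
#'
#' @param spec Named list or YAML file path.
#' @param out_dir Output directory (created if needed).
#' @return The mode's main result, invisibly (fit object, results table,
#'   trial list or file paths).
#' @export
run_experiment <- function(spec, out_dir) {
  if (is.character(spec) && length(spec) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML experiment files needs the 'yaml' package")
    spec <- yaml::read_yaml(spec)
  }
  if (is.null(spec$mode))
    stop("experiment config error: missing required field 'mode'")
  mode <- match.arg(spec$mode,
                    c("synth", "train-scratch", "pretrain-sup",
                      "pretrain-ssl", "finetune", "ablate-augment",
                      "inspect"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(spec$seed %||% 1L)
  manifest <- list(mode = mode, seed = seed, spec = spec,
                   package_version = as.character(utils::packageVersion("eegpatch")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  load_trials <- function() {
    trials <- if (!is.null(spec$synth))
      synth_generate(do.call(synth_config,
                             utils::modifyList(spec$synth %||% list(),
                                               list(rng_seed = seed))))
    else if (!is.null(spec$sessions))
      unlist(lapply(spec$sessions, read_session), recursive = FALSE)
    else stop("experiment config error: missing required field ",
              "'sessions' (or inline 'synth')")
    if (!identical(spec$preprocess, FALSE)) {
      if (isTRUE(spec$bandpass))
        trials <- lapply(trials, bandpass_filter)
      sess <- vapply(trials, function(t) t$session_id, character(1))
      trials <- unlist(lapply(split(trials, sess),
                              function(ts) session_zscore(ts)$trials),
                       recursive = FALSE, use.names = FALSE)
    }
    trials
  }
  build <- function(ctor, field, extra = list()) {
    do.call(ctor, utils::modifyList(spec[[field]] %||% list(), extra))
  }

  if (mode == "synth") {
    trials <- synth_generate(build(synth_config, "synth",
                                   list(rng_seed = seed)))
    sess <- vapply(trials, function(t) t$session_id, character(1))
    paths <- vapply(split(trials, sess), function(ts) {
      p <- file.path(out_dir, paste0(ts[[1L]]$session_id, ".json"))
      write_session(ts, p)
      p
    }, character(1))
    return(invisible(paths))
  }

  if (mode == "ablate-augment") {
    trials <- load_trials()
    config <- build(eegpatch_config, "model")
    policy <- build(train_policy, "policy", list(rng_seed = seed))
    res <- ablate_augment(trials, config, policy,
                          crop_window = spec$crop_window %||% 512L,
                          seeds = spec$seeds %||% 1:3,
                          verbose = isTRUE(spec$verbose))
    utils::write.csv(res, file.path(out_dir, "ablation.csv"),
                     row.names = FALSE)
    return(invisible(res))
  }

  if (mode == "inspect") {
    if (is.null(spec$checkpoint))
      stop("experiment config error: missing required field 'checkpoint'")
    model <- load_model(spec$checkpoint)
    trials <- load_trials()
    utils::write.csv(data.frame(filter = seq_len(model$config$d_model),
                                dominant_hz = filter_spectra(model)),
                     file.path(out_dir, "filter_spectra.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(pos_similarity(model)),
                     file.path(out_dir, "pos_similarity.csv"))
    n_show <- min(length(trials), spec$n_trials %||% 2L)
    files <- vapply(seq_len(n_show), function(i) {
      am <- attention_maps(model, trials[[i]])
      ro <- attention_rollout(am$attn, am$channel, am$slot)
      render_importance_map(ro, file.path(out_dir,
                                          sprintf("rollout_%02d.png", i)),
                            main = paste("trial", i, "-",
                                         trials[[i]]$label))
    }, character(1))
    return(invisible(files))
  }

  # training modes
  trials <- load_trials()
  config <- build(eegpatch_config, "model")
  policy <- if (mode == "pretrain-sup")
    build(pretrain_policy, "policy", list(rng_seed = seed))
  else build(train_policy, "policy", list(rng_seed = seed))
  augment <- build(augment_config, "augment")
  objective <- if (mode == "pretrain-ssl") "ssl" else "supervised"
  init <- NULL
  if (mode == "finetune") {
    if (is.null(spec$checkpoint))
      stop("experiment config error: missing required field 'checkpoint'")
    pre <- load_model(spec$checkpoint)
    montage <- unique(unlist(lapply(trials, function(t) t$channel_names)))
    n_classes <- length(unique(trial_labels(trials)))
    init <- transfer_weights(pre, montage, n_classes,
                             n_slots = augment$crop_window %/% pre$config$D,
                             seed = seed)
  }
  label_map <- if (mode == "pretrain-sup" && isTRUE(spec$amalgamate))
    label_map_default() else NULL
  fit <- eegpatch(trials, objective = objective, config = config,
                  policy = policy, augment = augment, init = init,
                  label_map = label_map, verbose = isTRUE(spec$verbose))
  utils::write.csv(fit$log, file.path(out_dir, "log.csv"),
                   row.names = FALSE)
  save_model(fit, file.path(out_dir, "model.rds"))
  last <- fit$log[nrow(fit$log), ]
  jsonlite::write_json(list(final_loss = last$loss,
                            final_accuracy = last$accuracy,
                            epochs = nrow(fit$log),
                            parameters = count_params(fit)),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(fit)
}
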