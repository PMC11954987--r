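#' Dominant frequencies of the learned embedding filters
#'
#' Each row of the patch-embedding matrix acts as a temporal filter of
#' length `D`. The dominant frequency of a filter is the location of the
#' magnitude-spectrum peak over the nonzero frequency bins, converted to Hz
#' by `bin * fs / D` (one cycle per patch = `fs / D` Hz; for D = 64 at
#' 250 Hz, `k` cycles per patch is `3.90625 * k` Hz, approximately `4k`).
#' A filter with no nonzero-bin energy (a constant row) is reported as
#' 0 Hz.
#'
#' @param W_E d_model x D embedding matrix (or an `eegpatch` model).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length d_model: dominant frequency per filter.
#' @export
filter_spectra <- function(W_E, fs = 250) {
  if (inherits(W_E, "eegpatch")) W_E <- W_E$params$W_E
  D <- ncol(W_E)
  nb <- D %/% 2L
  vapply(seq_len(nrow(W_E)), function(r) {
    mag <- Mod(stats::fft(W_E[r, ]))[2L:(nb + 1L)]
    if (max(mag) <= .Machine$double.eps * D) return(0)
    which.max(mag) * fs / D
  }, numeric(1))
}

#' Cosine similarity of learned sensor positional embeddings
#'
#' Collapses each channel's per-time-slot positional embeddings to one
#' vector by averaging over slots, then returns the channel-by-channel
#' cosine-similarity matrix (symmetric, unit diagonal).
#'
#' @param object An `eegpatch` model (or a positional-registry matrix with
#'   `"CH@slot"` row names).
#' @param montage Channels to include (default: all registered channels).
#' @return Symmetric channels x channels matrix of cosine similarities.
#' @export
pos_similarity <- function(object, montage = NULL) {
  pos <- if (inherits(object, "eegpatch")) object$params$pos else object
  keys <- setdiff(rownames(pos), "CLS")
  pos <- pos[keys, , drop = FALSE]
  chans <- sub("@.*$", "", keys)
  if (is.null(montage)) montage <- unique(chans)
  montage <- toupper(trimws(montage))
  V <- t(vapply(montage, function(ch) {
    rows <- pos[chans == ch, , drop = FALSE]
    if (!nrow(rows)) stop("channel ", ch, " not in the positional registry")
    colMeans(rows)
  }, numeric(ncol(pos))))
  nrm <- sqrt(rowSums(V^2))
  S <- (V / nrm) %*% t(V / nrm)
  dimnames(S) <- list(montage, montage)
  S
}

#' Attention rollout
#'
#' Aggregates per-layer attention into token-to-token attribution by the
#' rollout recursion: heads are averaged per layer, the residual connection
#' is accounted for as `A~ = (A + I) / 2` with rows renormalized, and the
#' corrected matrices are multiplied across layers (last layer first). The
#' per-patch importance is the classification-token row.
#'
#' @param attn List of per-layer attention matrices (square,
#'   row-stochastic; 3-d `heads x N x N` arrays are head-averaged first).
#' @param channel,slot Optional per-patch provenance (as returned by
#'   [forward_window()] with `collect_attention = TRUE`) used to shape the
#'   cls-row importance into a channel x slot grid.
#' @return A `rollout_map`: list with `matrix` ((N+1) x (N+1), rows summing
#'   to 1) and, when provenance is given, `importance` (channels x slots).
#' @export
attention_rollout <- function(attn, channel = NULL, slot = NULL) {
  stopifnot(is.list(attn), length(attn) >= 1L)
  mats <- lapply(attn, function(A) {
    if (length(dim(A)) == 3L) A <- apply(A, c(2L, 3L), mean)
    if (!is.matrix(A) || nrow(A) != ncol(A))
      stop("attention matrices must be square")
    if (max(abs(rowSums(A) - 1)) > 1e-6)
      stop("attention matrices must be row-stochastic")
    At <- (A + diag(nrow(A))) / 2
    At / rowSums(At)
  })
  R <- mats[[length(mats)]]
  for (b in rev(seq_len(length(mats) - 1L))) R <- R %*% mats[[b]]
  out <- list(matrix = R)
  if (!is.null(channel) && !is.null(slot)) {
    imp <- R[1L, -1L]
    chans <- unique(channel)
    slots <- sort(unique(slot))
    G <- matrix(NA_real_, length(chans), length(slots),
                dimnames = list(chans, slots))
    for (i in seq_along(imp)) G[channel[i], slot[i]] <- imp[i]
    out$importance <- G
  }
  structure(out, class = "rollout_map")
}

#' Render a patch-importance heatmap
#'
#' Writes a channel-by-time-slot heatmap of rollout importance to a PNG
#' file, optionally overlaying the trial's signal traces; brighter cells
#' mark patches more important for the classification.
#'
#' @param rollout A `rollout_map` with an `importance` grid.
#' @param file Output PNG path.
#' @param main Plot title.
#' @return The file path, invisibly.
#' @export
render_importance_map <- function(rollout, file, main = "attention rollout") {
  stopifnot(inherits(rollout, "rollout_map"), !is.null(rollout$importance))
  G <- rollout$importance
  grDevices::png(file, width = 720, height = 360)
  on.exit(grDevices::dev.off())
  graphics::image(x = seq_len(ncol(G)), y = seq_len(nrow(G)), z = t(G),
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "time slot", ylab = "", yaxt = "n", main = main)
  graphics::axis(2, at = seq_len(nrow(G)), labels = rownames(G), las = 1)
  invisible(file)
}

#' Per-layer attention maps for one trial
#'
#' Runs the model in evaluation mode and returns the head-averaged
#' attention matrix of every encoder block, plus patch provenance — the
#' input [attention_rollout()] expects.
#'
#' @param object A fitted `eegpatch` model.
#' @param trial An [eeg_trial()].
#' @return List with `attn` (per-block matrices), `channel`, `slot`,
#'   `prob` (predicted class probabilities).
#' @export
attention_maps <- function(object, trial) {
  stopifnot(is.eeg_trial(trial))
  crop <- object$augment$crop_window %||% (object$n_slots * object$config$D)
  x <- augment_time_shift(trial$signal, min(crop, ncol(trial$signal)),
                          center = TRUE)
  r <- forward_window(object, x, trial$channel_names, mode = "classify",
                      collect_attention = TRUE)
  list(attn = r$attn, channel = r$channel, slot = r$slot, prob = r$value)
}
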