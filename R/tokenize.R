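#' Tokenize a multichannel window into channel-pure patches
#'
#' Slices a channels-by-time signal window into contiguous, single-channel
#' patches of `D` samples in channel-major order (all time slots of the
#' first channel, then the second, ...). Trailing `T_w %% D` samples of each
#' channel are discarded, so the number of patches is `N = C * floor(T_w/D)`.
#'
#' @param x Numeric matrix (channels x samples) or an [eeg_trial()].
#' @param D Patch length in samples.
#' @param channel_names Channel labels; defaults to `rownames(x)` or the
#'   trial's channel names.
#' @return A `patch_seq`: list with `patches` (N x D matrix), `channel`
#'   (length-N channel label per patch), `slot` (1-based time-slot index per
#'   patch) and `n_slots`.
#' @examples
#' ps <- tokenize(matrix(seq_len(2 * 10), 2, byrow = TRUE), D = 4,
#'                channel_names = c("C3", "C4"))
#' ps$patches
#' @export
tokenize <- function(x, D, channel_names = NULL) {
  if (is.eeg_trial(x)) {
    channel_names <- x$channel_names
    x <- x$signal
  }
  if (is.null(channel_names)) channel_names <- rownames(x)
  stopifnot(is.matrix(x), !is.null(channel_names),
            length(channel_names) == nrow(x))
  D <- as.integer(D)
  T_w <- ncol(x)
  if (T_w < D)
    stop("invalid input: window length ", T_w, " is shorter than patch size ", D)
  S <- T_w %/% D
  C <- nrow(x)
  patches <- matrix(0, C * S, D)
  for (c in seq_len(C))
    patches[((c - 1L) * S + 1L):(c * S), ] <-
      matrix(x[c, seq_len(S * D)], S, D, byrow = TRUE)
  structure(list(patches = patches,
                 channel = rep(channel_names, each = S),
                 slot = rep(seq_len(S), C),
                 n_slots = S),
            class = "patch_seq")
}
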