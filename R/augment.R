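#' Per-trial augmentation configuration
#'
#' Switches and parameters for the four per-trial augmentation operators and
#' pre-training channel subsampling. Noise/shift/scale magnitudes are in
#' z-scored signal units, since augmentation runs after session z-scoring in
#' the training pipeline. `crop_window` is the length in samples of the
#' window fed to the model; with time-shift augmentation enabled, the window
#' start is redrawn uniformly every epoch, otherwise it is fixed at the
#' center of the trial.
#'
#' @param noise,dc_shift,amplitude_scale,time_shift Logical switches.
#' @param noise_sigma,dc_sigma Standard deviations of the additive Gaussian
#'   noise and of the per-trial DC offset (defaults 0.1).
#' @param scale_mu,scale_sigma Mean (1) and sd (0.1) of the per-trial
#'   amplitude scale factor.
#' @param crop_window Window length in samples (default 512, i.e. ~2 s of
#'   250 Hz signal).
#' @param channel_keep_prob Independent keep probability for pre-training
#'   channel subsampling (1 = keep all; at least one channel is always kept).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(noise = FALSE, dc_shift = FALSE,
                           amplitude_scale = FALSE, time_shift = TRUE,
                           noise_sigma = 0.1, dc_sigma = 0.1,
                           scale_mu = 1, scale_sigma = 0.1,
                           crop_window = 512L, channel_keep_prob = 1) {
  stopifnot(noise_sigma >= 0, dc_sigma >= 0, scale_sigma >= 0,
            crop_window >= 1, channel_keep_prob > 0, channel_keep_prob <= 1)
  structure(list(noise = isTRUE(noise), dc_shift = isTRUE(dc_shift),
                 amplitude_scale = isTRUE(amplitude_scale),
                 time_shift = isTRUE(time_shift),
                 noise_sigma = noise_sigma, dc_sigma = dc_sigma,
                 scale_mu = scale_mu, scale_sigma = scale_sigma,
                 crop_window = as.integer(crop_window),
                 channel_keep_prob = channel_keep_prob),
            class = "augment_config")
}

#' Augmentation operators
#'
#' Per-trial EEG augmentation primitives operating on a channels-by-time
#' signal matrix. All draws come from R's global random number generator;
#' seed with [set.seed()] for reproducibility.
#'
#' * `augment_noise()` adds element-wise independent Gaussian noise
#'   (mean 0, sd `sigma`).
#' * `augment_dc_shift()` adds one scalar `N(0, sigma^2)` draw to the whole
#'   trial, so relative channel amplitudes are preserved.
#' * `augment_scale()` multiplies the trial by one scalar drawn
#'   `N(mu, sigma^2)`.
#' * `augment_time_shift()` crops a `window`-sample slice at a uniformly
#'   random start (fresh each call), or at the center when `center = TRUE`
#'   (the deterministic evaluation-time rule).
#'
#' @param x Numeric matrix, channels x samples.
#' @param sigma,mu Distribution parameters (see above).
#' @param window Crop length in samples, `window <= ncol(x)`.
#' @param start Optional fixed 1-based start index (overrides randomness).
#' @param center Use the centered window instead of a random one.
#' @return A matrix of the same number of channels.
#' @name augmentation
NULL

#' @rdname augmentation
#' @export
augment_noise <- function(x, sigma = 0.1) {
  if (sigma == 0) return(x)
  x + matrix(stats::rnorm(length(x), 0, sigma), nrow(x), ncol(x))
}

#' @rdname augmentation
#' @export
augment_dc_shift <- function(x, sigma = 0.1) {
  if (sigma == 0) return(x)
  x + stats::rnorm(1L, 0, sigma)
}

#' @rdname augmentation
#' @export
augment_scale <- function(x, mu = 1, sigma = 0.1) {
  if (sigma == 0) return(x * mu)
  x * stats::rnorm(1L, mu, sigma)
}

#' @rdname augmentation
#' @export
augment_time_shift <- function(x, window, start = NULL, center = FALSE) {
  T_len <- ncol(x)
  window <- as.integer(window)
  if (window > T_len)
    stop("invalid parameter: window (", window,
         ") exceeds trial length (", T_len, ")")
  if (is.null(start)) {
    start <- if (center) (T_len - window) %/% 2L + 1L
             else sample.int(T_len - window + 1L, 1L)
  }
  x[, start:(start + window - 1L), drop = FALSE]
}

#' Randomly subsample the channels of a trial
#'
#' Pre-training channel subsampling: each channel is kept independently with
#' probability `keep_prob` (order preserved); if the draw would drop every
#' channel, one uniformly chosen channel is kept instead.
#'
#' @param trial An [eeg_trial()].
#' @param keep_prob Keep probability in (0, 1].
#' @return A trial whose channels are a subset of the input channels.
#' @export
subsample_channels <- function(trial, keep_prob = 1) {
  stopifnot(is.eeg_trial(trial), keep_prob > 0, keep_prob <= 1)
  if (keep_prob == 1) return(trial)
  C <- nrow(trial$signal)
  keep <- which(stats::runif(C) < keep_prob)
  if (!length(keep)) keep <- sample.int(C, 1L)
  out <- trial
  out$signal <- trial$signal[keep, , drop = FALSE]
  out$channel_names <- trial$channel_names[keep]
  out
}

# Compose the configured operators on one signal matrix (training mode:
# random crop when time_shift is on, fixed centered crop otherwise).
apply_augment <- function(x, cfg, training = TRUE) {
  x <- augment_time_shift(x, cfg$crop_window,
                          center = !(training && cfg$time_shift))
  if (training) {
    if (cfg$amplitude_scale) x <- augment_scale(x, cfg$scale_mu, cfg$scale_sigma)
    if (cfg$dc_shift) x <- augment_dc_shift(x, cfg$dc_sigma)
    if (cfg$noise) x <- augment_noise(x, cfg$noise_sigma)
  }
  x
}
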