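#' Synthetic motor-imagery EEG configuration
#'
#' Describes a synthetic dataset emulating sensorimotor-rhythm
#' motor-imagery EEG: band-limited alpha (8-12 Hz) and beta (12-35 Hz)
#' oscillations over 1/f-shaped Gaussian background noise, with
#' class-dependent, hemispherically lateralized band-power *decreases*
#' (event-related desynchronization) on designated motor-cortex channels —
#' C3 for right-hand imagery, C4 for left-hand imagery, Cz for feet, both
#' C3 and C4 for both-hands; REST and TONGUE are unmodulated.
#'
#' @param classes Subset of `LEFT_HAND`, `RIGHT_HAND`, `FEET`, `REST`,
#'   `BOTH_HANDS`, `TONGUE`.
#' @param n_subjects Subjects (one session each).
#' @param trials_per_class Trials per class per subject.
#' @param channels Montage (must contain the channels the configured
#'   classes modulate).
#' @param fs Sampling rate in Hz.
#' @param trial_seconds Trial length in seconds (`fs * trial_seconds` must
#'   be integral).
#' @param effect_size Relative band-power modulation in `[0, 1]`: on
#'   modulated channels the oscillation amplitude is scaled by
#'   `1 - effect_size`. 0 = null data, 1 = complete suppression.
#' @param noise_exponent Spectral exponent of the 1/f background.
#' @param rng_seed Seed; the same seed yields a bit-identical dataset.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(classes = c("LEFT_HAND", "RIGHT_HAND"),
                         n_subjects = 4L, trials_per_class = 25L,
                         channels = c("C3", "CZ", "C4"), fs = 250,
                         trial_seconds = 4, effect_size = 0.5,
                         noise_exponent = 1, rng_seed = 1L) {
  channels <- toupper(trimws(channels))
  stopifnot(effect_size >= 0, effect_size <= 1, n_subjects >= 1,
            trials_per_class >= 1, fs > 0,
            abs(fs * trial_seconds - round(fs * trial_seconds)) < 1e-9)
  needed <- class_modulation_channels(classes)
  missing <- setdiff(needed, channels)
  if (length(missing))
    stop("channel_set is missing channel(s) required by the configured ",
         "classes: ", paste(missing, collapse = ", "))
  structure(list(classes = classes, n_subjects = as.integer(n_subjects),
                 trials_per_class = as.integer(trials_per_class),
                 channels = channels, fs = fs,
                 trial_seconds = trial_seconds,
                 effect_size = effect_size,
                 noise_exponent = noise_exponent,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

class_modulation_channels <- function(classes) {
  map <- list(LEFT_HAND = "C4", RIGHT_HAND = "C3", FEET = "CZ",
              BOTH_HANDS = c("C3", "C4"), REST = character(0),
              TONGUE = character(0))
  unknown <- setdiff(classes, names(map))
  if (length(unknown))
    stop("unknown synthetic class(es): ", paste(unknown, collapse = ", "))
  unique(unlist(map[classes]))
}

# 1/f^a-shaped Gaussian noise, normalized to unit standard deviation.
one_over_f_noise <- function(n, exponent = 1) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                       # mirrored frequency index
  shape <- f^(-exponent / 2)
  shape[1L] <- 0                                 # no DC
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate synthetic motor-imagery EEG trials
#'
#' Each trial is a per-subject gain times (1/f background + alpha + beta
#' oscillations with random frequency and phase per channel); on the
#' modulated channel(s) of the trial's class the oscillation amplitudes are
#' scaled by `1 - effect_size` (desynchronization). One session per
#' subject; fully reproducible from `config$rng_seed`.
#'
#' @param config A [synth_config()].
#' @return List of [eeg_trial()]s (dataset_id `"synth"`).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$rng_seed)
  T_len <- as.integer(round(config$fs * config$trial_seconds))
  tt <- seq_len(T_len) / config$fs
  trials <- list()
  for (s in seq_len(config$n_subjects)) {
    gain <- abs(stats::rnorm(1, 1, 0.1))
    subject <- sprintf("sub%02d", s)
    session <- sprintf("%s.sess01", subject)
    for (cls in config$classes) {
      mod_ch <- class_modulation_channels(cls)
      for (r in seq_len(config$trials_per_class)) {
        sig <- matrix(0, length(config$channels), T_len,
                      dimnames = list(config$channels, NULL))
        for (ci in seq_along(config$channels)) {
          ch <- config$channels[ci]
          att <- if (ch %in% mod_ch) 1 - config$effect_size else 1
          alpha <- sin(2 * pi * stats::runif(1, 9, 11) * tt +
                         stats::runif(1, 0, 2 * pi))
          beta <- sin(2 * pi * stats::runif(1, 18, 24) * tt +
                        stats::runif(1, 0, 2 * pi))
          sig[ci, ] <- gain *
            (one_over_f_noise(T_len, config$noise_exponent) +
               att * (1.0 * alpha + 0.5 * beta))
        }
        trials[[length(trials) + 1L]] <-
          eeg_trial(sig, config$channels, config$fs, label = cls,
                    subject_id = subject, session_id = session,
                    dataset_id = "synth")
      }
    }
  }
  trials
}

#' Tiny deterministic worked fixture
#'
#' Twelve 3-channel, 4-second trials at 250 Hz with integer-derived
#' sinusoidal signals (no randomness, platform-stable checksum) and
#' balanced LEFT_HAND / RIGHT_HAND labels. Intended for unit tests of the
#' tokenizer, normalization and container round trips.
#'
#' @return List of 12 [eeg_trial()]s.
#' @export
worked_fixture <- function() {
  channels <- c("C3", "CZ", "C4")
  fs <- 250
  T_len <- 1000L
  tt <- seq_len(T_len)
  lapply(seq_len(12L), function(k) {
    sig <- t(vapply(seq_along(channels), function(c)
      sin(2 * pi * (4 + c + (k %% 3)) * tt / fs) +
        0.25 * cos(2 * pi * (10 + 2 * c + k) * tt / fs) +
        0.01 * c * (k %% 5),
      numeric(T_len)))
    eeg_trial(sig, channels, fs,
              label = if (k %% 2 == 0) "RIGHT_HAND" else "LEFT_HAND",
              subject_id = "sub01", session_id = "sub01.sess01",
              dataset_id = "fixture")
  })
}
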