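#' Zero-phase IIR bandpass filter for an EEG trial
#'
#' Applies a 4th-order Butterworth bandpass forward and backward
#' (zero phase) to every channel. The default band, 8-45 Hz, covers the
#' alpha (8-12 Hz), beta (12-35 Hz) and low gamma (>= 35 Hz) rhythms that
#' carry the motor-imagery signal while rejecting drift and line noise.
#'
#' @param trial An [eeg_trial()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @return A filtered trial of identical shape.
#' @export
bandpass_filter <- function(trial, low_hz = 8, high_hz = 45) {
  stopifnot(is.eeg_trial(trial))
  ny <- trial$fs / 2
  if (!is.finite(low_hz) || low_hz <= 0)
    stop("invalid band edge: low_hz = ", low_hz, " must be > 0")
  if (high_hz <= low_hz)
    stop("invalid band edge: high_hz = ", high_hz,
         " must exceed low_hz = ", low_hz)
  if (high_hz >= ny)
    stop("invalid band edge: high_hz = ", high_hz,
         " must be below the Nyquist frequency ", ny)
  bf <- signal::butter(4, c(low_hz, high_hz) / ny, type = "pass")
  out <- trial
  for (c in seq_len(nrow(trial$signal)))
    out$signal[c, ] <- signal::filtfilt(bf, trial$signal[c, ])
  out
}

# Fourier-domain resampling of one real-valued series to m samples.
# Exact zero phase; band-limited content below the smaller Nyquist is kept.
fft_resample_vec <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  kmax <- floor(min(n, m) / 2)
  Y[1L] <- X[1L]
  if (kmax >= 1L) {
    ks <- seq_len(max(kmax - 1L, 0L))
    if (length(ks)) {
      Y[ks + 1L] <- X[ks + 1L]
      Y[m - ks + 1L] <- X[n - ks + 1L]
    }
    # shared Nyquist-edge bin: keep it real so the output stays real
    if (min(n, m) %% 2L == 0L) {
      Y[kmax + 1L] <- Re(X[kmax + 1L])
      if (m > n) Y[m - kmax + 1L] <- Re(X[kmax + 1L])
    } else {
      Y[kmax + 1L] <- X[kmax + 1L]
      Y[m - kmax + 1L] <- X[n - kmax + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample an EEG trial to a new sampling rate
#'
#' Fourier-domain resampling: exact zero phase, output length
#' `T_out = round(T * target_fs / fs)`, band-limited content below
#' `min(fs, target_fs)/2` preserved. Channel count and order are unchanged.
#'
#' @param trial An [eeg_trial()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return The resampled trial with `fs == target_fs`.
#' @export
resample_trial <- function(trial, target_fs) {
  stopifnot(is.eeg_trial(trial))
  target_fs <- as.numeric(target_fs)
  if (!is.finite(target_fs) || target_fs <= 0)
    stop("'target_fs' must be > 0")
  if (isTRUE(all.equal(target_fs, trial$fs))) return(trial)
  n <- ncol(trial$signal)
  m <- as.integer(round(n * target_fs / trial$fs))
  if (m < 1L) stop("resampling would leave fewer than one sample")
  out_sig <- matrix(0, nrow(trial$signal), m,
                    dimnames = list(trial$channel_names, NULL))
  for (c in seq_len(nrow(trial$signal)))
    out_sig[c, ] <- fft_resample_vec(trial$signal[c, ], m)
  out <- trial
  out$signal <- out_sig
  out$fs <- target_fs
  out
}

#' Session-wise channel z-scoring
#'
#' Standardizes each channel to zero mean and unit variance using statistics
#' pooled over *all* samples of *all* trials of one recording session
#' (population standard deviation). Training and evaluation sessions must be
#' normalized separately by calling this on each session's trials.
#'
#' @param trials List of [eeg_trial()]s from a single session (same
#'   `session_id`, `channel_names`, `fs`).
#' @return A list with `trials` (normalized) and `stats`, a data frame with
#'   columns `channel`, `mean`, `sd` (one row per channel; write it out with
#'   [utils::write.csv()] if a CSV export is needed).
#' @export
session_zscore <- function(trials) {
  check_session_consistency(trials, "session_zscore input")
  sid <- unique(vapply(trials, function(t) t$session_id, character(1)))
  if (length(sid) > 1L)
    stop("session_zscore input mixes sessions: ", paste(sid, collapse = ", "))
  chn <- trials[[1L]]$channel_names
  big <- do.call(cbind, lapply(trials, function(t) t$signal))
  mu <- rowMeans(big)
  sd_pop <- sqrt(rowMeans((big - mu)^2))
  if (any(sd_pop == 0))
    stop("degenerate channel with zero variance in session: ",
         paste(chn[sd_pop == 0], collapse = ", "))
  out <- lapply(trials, function(t) {
    t$signal <- (t$signal - mu) / sd_pop
    t
  })
  list(trials = out,
       stats = data.frame(channel = chn, mean = mu, sd = sd_pop,
                          row.names = NULL))
}
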