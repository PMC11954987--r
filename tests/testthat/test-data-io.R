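test_that("trial construction validates invariants and normalizes names", {
  tr <- eeg_trial(matrix(1:6, 2), c("c3", " cz"), fs = 250)
  expect_identical(tr$channel_names, c("C3", "CZ"))
  expect_error(eeg_trial(matrix(1:6, 2), c("C3", "C3"), 250), "unique")
  expect_error(eeg_trial(matrix(1:6, 2), c("C3",), 250))
  expect_error(eeg_trial(matrix(1:6, 2), c("C3", "C4"), 0), "positive")
})

test_that("session write/read round-trips signal and metadata losslessly", {
  set.seed(1)
  trials <- lapply(1:3, function(i)
    eeg_trial(matrix(rnorm(3 * 40), 3), c("C3", "CZ", "C4"), 250,
              label = c("LEFT_HAND", "RIGHT_HAND", NA)[i],
              subject_id = "sub01", session_id = "sub01.s1",
              dataset_id = "dsA"))
  path <- withr::local_tempfile(fileext = ".json")
  write_session(trials, path)
  back <- read_session(path)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$signal, trials[[i]]$signal, tolerance = 1e-12)
    expect_identical(back[[i]]$label, trials[[i]]$label)
    expect_identical(back[[i]]$subject_id, trials[[i]]$subject_id)
    expect_identical(back[[i]]$session_id, trials[[i]]$session_id)
    expect_identical(back[[i]]$dataset_id, trials[[i]]$dataset_id)
    expect_identical(back[[i]]$fs, trials[[i]]$fs)
    expect_identical(back[[i]]$channel_names, trials[[i]]$channel_names)
  }
})

test_that("malformed containers and inconsistent sessions are rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(channel_names = c("C3"), trials = list()),
                       path, auto_unbox = TRUE)
  expect_error(read_session(path), "fs")
  t1 <- random_trial(2, 50, channels = c("C3", "C4"))
  t2 <- random_trial(2, 50, channels = c("C3", "CZ"))
  expect_error(write_session(list(t1, t2), tempfile()),
               "inconsistent channel_names")
})

test_that("bandpass preserves in-band and attenuates out-of-band content", {
  fs <- 250
  tt <- (0:999) / fs
  mk <- function(f) eeg_trial(rbind(sin(2 * pi * f * tt)), "C3", fs)
  # oracle: squared magnitude response of the designed filter (the filter
  # runs forward and backward, so the amplitude response is |H|^2)
  bf <- signal::butter(4, c(8, 45) / (fs / 2), type = "pass")
  H <- function(f) {
    h <- signal::freqz(bf$b, bf$a, Fs = fs)
    abs(h$h[which.min(abs(h$f - f))])^2
  }
  rms <- function(x) sqrt(mean(x^2))
  mid <- 150:850  # interior samples, away from filter edge transients
  out25 <- bandpass_filter(mk(25))$signal[1, ]
  expect_gt(H(25), 0.99)
  expect_lt(abs(rms(out25[mid]) / rms(mk(25)$signal[1, mid]) - 1), 0.1)
  out2 <- bandpass_filter(mk(2))$signal[1, ]
  expect_lt(H(2), 10^(-20 / 10))
  atten_db <- 20 * log10(rms(out2[mid]) / rms(mk(2)$signal[1, mid]))
  expect_lt(atten_db, -20)
  # zero in, zero out; shape and channel order unchanged
  z <- bandpass_filter(eeg_trial(matrix(0, 2, 500), c("C3", "C4"), fs))
  expect_equal(z$signal, matrix(0, 2, 500, dimnames = list(c("C3", "C4"), NULL)))
  expect_error(bandpass_filter(mk(25), low_hz = 0), "low_hz")
  expect_error(bandpass_filter(mk(25), low_hz = 50, high_hz = 45), "high_hz")
  expect_error(bandpass_filter(mk(25), high_hz = 200), "Nyquist")
})

test_that("resampling fixes length by round(T * r) and preserves content", {
  tr <- random_trial(2, 1000, fs = 250, channels = c("C3", "C4"))
  expect_identical(resample_trial(tr, 250), tr)
  half <- resample_trial(eeg_trial(matrix(rnorm(1000), 1), "C3", 500), 250)
  expect_identical(ncol(half$signal), 500L)
  expect_identical(half$fs, 250)
  # 10 Hz tone resampled 512 -> 250 Hz matches the analytic sinusoid
  fs0 <- 512
  x <- sin(2 * pi * 10 * (0:2047) / fs0)
  y <- resample_trial(eeg_trial(rbind(x), "C3", fs0), 250)
  ref <- sin(2 * pi * 10 * (0:(ncol(y$signal) - 1)) / 250)
  expect_gt(cor(y$signal[1, ], ref), 0.99)
  expect_error(resample_trial(tr, -1), "target_fs")
})

test_that("session z-score pools statistics over trials, per channel", {
  x <- eeg_trial(rbind(c(1, 2, 3)), "C3", 10)
  z <- session_zscore(list(x))
  expect_equal(mean(z$trials[[1]]$signal), 0, tolerance = 1e-12)
  expect_equal(mean(z$trials[[1]]$signal^2), 1, tolerance = 1e-12)
  expect_equal(z$stats$sd, sqrt(2 / 3))   # population formula

  set.seed(42)
  trials <- lapply(1:4, function(i) random_trial(3, 200))
  z <- session_zscore(trials)
  big <- do.call(cbind, lapply(z$trials, function(t) t$signal))
  expect_lt(max(abs(rowMeans(big))), 1e-6)
  expect_lt(max(abs(rowMeans(big^2) - 1)), 1e-6)

  flat <- random_trial(2, 100, channels = c("C3", "C4"))
  flat$signal[2, ] <- 5
  expect_error(session_zscore(list(flat)), "C4")
})

test_that("z-score is idempotent and invariant to per-channel affine maps", {
  set.seed(7)
  trials <- lapply(1:3, function(i) random_trial(3, 150))
  once <- session_zscore(trials)$trials
  twice <- session_zscore(once)$trials
  for (i in seq_along(trials))
    expect_lt(max(abs(once[[i]]$signal - twice[[i]]$signal)), 1e-5)
  a <- c(2.5, 0.3, 7); b <- c(-1, 4, 0.2)
  warped <- lapply(trials, function(t) {
    t$signal <- t$signal * a + b
    t
  })
  zw <- session_zscore(warped)$trials
  for (i in seq_along(trials))
    expect_lt(max(abs(once[[i]]$signal - zw[[i]]$signal)), 1e-6)
})

test_that("independently normalized sessions do not pool to unit variance", {
  set.seed(11)
  s1 <- lapply(1:3, function(i) random_trial(2, 100, channels = c("C3", "C4"),
                                             session = "A"))
  s2 <- lapply(1:3, function(i) {
    t <- random_trial(2, 100, channels = c("C3", "C4"), session = "B")
    t$signal <- t$signal * 6 + 3
    t
  })
  z1 <- session_zscore(s1)$trials
  z2 <- session_zscore(s2)$trials
  pooled_var <- function(ts) {
    big <- do.call(cbind, lapply(ts, function(t) t$signal))
    rowMeans(big^2) - rowMeans(big)^2
  }
  # separate normalization: each session is exactly unit variance
  expect_equal(unname(pooled_var(z1)), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(pooled_var(z2)), c(1, 1), tolerance = 1e-10)
  # joint (mis)normalization of the union leaves the within-session
  # variances away from 1 for sessions on different scales — the brute-force
  # reason the two sessions must be normalized independently
  joint <- c(s1, s2)
  joint <- lapply(joint, function(t) { t$session_id <- "AB"; t })
  zj <- session_zscore(joint)$trials
  expect_false(isTRUE(all.equal(unname(pooled_var(zj[1:3])), c(1, 1),
                                tolerance = 1e-3)))
  expect_false(isTRUE(all.equal(unname(pooled_var(zj[4:6])), c(1, 1),
                                tolerance = 1e-3)))
  expect_error(session_zscore(c(s1, s2)), "mixes sessions")
})
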