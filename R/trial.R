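#' Construct an EEG trial
#'
#' A trial is one EEG recording segment: a channels-by-time signal matrix plus
#' the montage labels, sampling rate, class label, and subject / session /
#' dataset identifiers. Channel names are normalized to upper-case 10-20
#' labels on construction.
#'
#' @param signal Numeric matrix, channels x samples.
#' @param channel_names Character vector of montage labels, one per row of
#'   `signal` (10-20 convention, e.g. `"C3"`, `"Cz"`, `"C4"`).
#' @param fs Sampling rate in Hz.
#' @param label Class label (character) or `NA` for unlabeled trials.
#' @param subject_id,session_id,dataset_id Opaque identifier strings.
#' @return An object of class `eeg_trial`.
#' @examples
#' tr <- eeg_trial(matrix(rnorm(3 * 100), 3), c("C3", "Cz", "C4"), fs = 250,
#'                 label = "LEFT_HAND")
#' tr
#' @export
eeg_trial <- function(signal, channel_names, fs, label = NA_character_,
                      subject_id = "S01", session_id = "S01.R01",
                      dataset_id = "local") {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("'signal' must be a numeric matrix (channels x samples)")
  if (nrow(signal) < 1L || ncol(signal) < 1L)
    stop("'signal' must have at least one channel and one sample")
  channel_names <- toupper(trimws(as.character(channel_names)))
  if (length(channel_names) != nrow(signal))
    stop("length(channel_names) must equal nrow(signal)")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique within a trial: duplicated ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be a positive sampling rate in Hz")
  storage.mode(signal) <- "double"
  rownames(signal) <- channel_names
  structure(list(signal = signal,
                 channel_names = channel_names,
                 fs = fs,
                 label = as.character(label),
                 subject_id = as.character(subject_id),
                 session_id = as.character(session_id),
                 dataset_id = as.character(dataset_id)),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> %d ch x %d samples @ %g Hz (%.3g s), label=%s, %s/%s/%s\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs,
              if (is.na(x$label)) "<none>" else x$label,
              x$dataset_id, x$subject_id, x$session_id))
  invisible(x)
}

#' @rdname eeg_trial
#' @param x Object to test.
#' @export
is.eeg_trial <- function(x) inherits(x, "eeg_trial")

trial_labels <- function(trials) vapply(trials, function(t) t$label, character(1))

check_session_consistency <- function(trials, context = "session") {
  if (!length(trials)) stop("empty ", context)
  if (!all(vapply(trials, is.eeg_trial, logical(1))))
    stop("all elements must be eeg_trial objects")
  ref <- trials[[1L]]
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (!identical(tr$channel_names, ref$channel_names))
      stop(sprintf("inconsistent channel_names within %s (trial %d)", context, i))
    if (!isTRUE(all.equal(tr$fs, ref$fs)))
      stop(sprintf("inconsistent sampling rate within %s (trial %d)", context, i))
  }
  invisible(trials)
}

#' Write / read a session of EEG trials
#'
#' One file per recording session. The container is JSON with file-level
#' `fs` and `channel_names` and one record per trial holding the signal
#' matrix (row-major, full double precision) plus `label`, `subject_id`,
#' `session_id` and `dataset_id`. The round trip is lossless for the signal
#' (to double precision) and all metadata.
#'
#' @param trials List of [eeg_trial()] objects sharing `channel_names` and `fs`.
#' @param path File path (conventionally `.json`).
#' @return `write_session` returns `path` invisibly; `read_session` returns a
#'   list of `eeg_trial` objects.
#' @export
write_session <- function(trials, path) {
  check_session_consistency(trials, "session file")
  payload <- list(
    format = "eegpatch-session/1",
    fs = trials[[1L]]$fs,
    channel_names = trials[[1L]]$channel_names,
    trials = lapply(trials, function(tr) {
      list(label = tr$label, subject_id = tr$subject_id,
           session_id = tr$session_id, dataset_id = tr$dataset_id,
           signal = unname(tr$signal))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = TRUE),
    error = function(e) stop("malformed session container '", path, "': ",
                             conditionMessage(e)))
  for (field in c("fs", "channel_names", "trials"))
    if (is.null(obj[[field]]))
      stop("malformed session container '", path,
           "': missing required attribute '", field, "'")
  trials <- lapply(seq_along(obj$trials), function(i) {
    rec <- obj$trials[[i]]
    if (is.null(rec$signal))
      stop("malformed session container '", path, "': trial ", i,
           " missing 'signal'")
    sig <- rec$signal
    if (!is.matrix(sig)) sig <- matrix(sig, nrow = length(obj$channel_names))
    eeg_trial(sig, obj$channel_names, obj$fs,
              label = if (is.null(rec$label)) NA_character_ else rec$label,
              subject_id = rec$subject_id %||% "S01",
              session_id = rec$session_id %||% "S01.R01",
              dataset_id = rec$dataset_id %||% "local")
  })
  check_session_consistency(trials, paste0("session file '", path, "'"))
  trials
}

`%||%` <- function(a, b) if (is.null(a)) b else a
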