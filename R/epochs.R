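#' Epoched EEG container
#'
#' An `epoch_set` holds a trials x channels x samples tensor of epoched EEG
#' (microvolts), per-trial binary labels (1 = target), a time axis in seconds
#' relative to stimulus onset, channel names and the sampling rate.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param labels integer/numeric vector of 0/1, one per trial (1 = target).
#' @param time_axis numeric vector of sample times in seconds relative to
#'   stimulus onset; must be strictly increasing and uniform.
#' @param channel_names character vector, one name per channel.
#' @param sampling_rate sampling rate in Hz.
#' @param metadata optional named list of free-form metadata.
#'
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, time_axis, channel_names, sampling_rate,
                      metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_dpifuse("`data` must be a 3-d array (trials x channels x samples)",
                 "dpifuse_format_error")
  d <- dim(data)
  labels <- as.integer(labels)
  if (length(labels) != d[1L])
    stop_dpifuse(sprintf("length(labels) == %d but data has %d trials",
                         length(labels), d[1L]), "dpifuse_format_error")
  if (!all(labels %in% c(0L, 1L)))
    stop_dpifuse("labels must be binary (0 = non-target, 1 = target)",
                 "dpifuse_format_error")
  if (length(channel_names) != d[2L])
    stop_dpifuse(sprintf("%d channel names but data has %d channels",
                         length(channel_names), d[2L]), "dpifuse_format_error")
  if (length(time_axis) != d[3L])
    stop_dpifuse(sprintf("time axis length %d but data has %d samples",
                         length(time_axis), d[3L]), "dpifuse_format_error")
  dt <- diff(time_axis)
  if (any(dt <= 0) || (length(dt) > 1 && max(abs(dt - dt[1L])) > 1e-9))
    stop_dpifuse("time axis must be strictly increasing and uniform",
                 "dpifuse_format_error")
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    stop_dpifuse("sampling_rate must be a positive number",
                 "dpifuse_config_error")
  structure(
    list(data = data, labels = labels, time_axis = as.numeric(time_axis),
         channel_names = as.character(channel_names),
         sampling_rate = as.numeric(sampling_rate), metadata = metadata),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials (%d target / %d non-target), %d channels, %d samples\n",
    d[1L], sum(x$labels == 1L), sum(x$labels == 0L), d[2L], d[3L]))
  cat(sprintf("  time %.3f..%.3f s @ %g Hz\n",
              x$time_axis[1L], x$time_axis[length(x$time_axis)],
              x$sampling_rate))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(epochs) dim(epochs$data)[1L]

#' Subset an epoch set by trial index
#'
#' @param epochs an [epoch_set()].
#' @param idx trial indices (1-based) to keep.
#' @return an [epoch_set()] with the selected trials, all other fields kept.
#' @export
subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$time_axis, epochs$channel_names, epochs$sampling_rate,
            epochs$metadata)
}

#' Per-trial detector score container
#'
#' A `score_set` holds per-trial posterior probabilities of the target class
#' emitted by one heterogeneous information source (an EEG decoder, a
#' computer-vision detector, ...). The non-target posterior is always
#' `1 - posteriors` and is never stored.
#'
#' @param posteriors numeric vector of target posteriors in \[0, 1\].
#' @param labels binary 0/1 vector of true labels, same length.
#' @param trial_ids optional trial identifiers (default `0:(n-1)`).
#' @param source_id name of the emitting source.
#'
#' @return an object of class `score_set`.
#' @export
score_set <- function(posteriors, labels, trial_ids = NULL,
                      source_id = "source") {
  posteriors <- as.numeric(posteriors)
  labels <- as.integer(labels)
  n <- length(posteriors)
  if (n == 0L)
    stop_dpifuse("empty score set", "dpifuse_format_error")
  if (length(labels) != n)
    stop_dpifuse("posteriors and labels differ in length",
                 "dpifuse_format_error")
  bad <- which(!is.finite(posteriors) | posteriors < 0 | posteriors > 1)
  if (length(bad))
    stop_dpifuse(sprintf("posterior outside [0,1] at row %d", bad[1L]),
                 "dpifuse_validation_error")
  if (!all(labels %in% c(0L, 1L)))
    stop_dpifuse("labels must be binary 0/1", "dpifuse_format_error")
  if (is.null(trial_ids)) trial_ids <- seq_len(n) - 1L
  if (anyDuplicated(trial_ids))
    stop_dpifuse("duplicate trial_id", "dpifuse_validation_error")
  structure(
    list(source_id = as.character(source_id), trial_ids = trial_ids,
         posteriors = posteriors, labels = labels),
    class = "score_set"
  )
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> source '%s': %d trials (%d target), posterior range [%.3f, %.3f]\n",
              x$source_id, length(x$posteriors), sum(x$labels == 1L),
              min(x$posteriors), max(x$posteriors)))
  invisible(x)
}

#' @export
length.score_set <- function(x) length(x$posteriors)

check_two_classes <- function(labels, what = "input") {
  if (length(unique(labels)) < 2L)
    stop_dpifuse(sprintf("%s contains a single class; both target and non-target trials are required", what),
                 "dpifuse_validation_error")
  invisible(TRUE)
}

# Check that several score sets describe the same trials in the same order.
check_aligned <- function(sources) {
  ref <- sources[[1L]]
  for (i in seq_along(sources)[-1L]) {
    s <- sources[[i]]
    if (length(s$trial_ids) != length(ref$trial_ids))
      stop_dpifuse("sources have differing numbers of trials",
                   "dpifuse_validation_error")
    mism <- which(s$trial_ids != ref$trial_ids)
    if (length(mism))
      stop_dpifuse(sprintf(
        "trial ids misaligned between sources '%s' and '%s' first at position %d (%s vs %s)",
        ref$source_id, s$source_id, mism[1L],
        ref$trial_ids[mism[1L]], s$trial_ids[mism[1L]]),
        "dpifuse_validation_error")
    if (any(s$labels != ref$labels))
      stop_dpifuse("labels disagree across sources for the same trials",
                   "dpifuse_validation_error")
  }
  invisible(TRUE)
}
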