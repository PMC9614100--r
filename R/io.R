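EPOCH_SCHEMA_VERSION <- "1.0"

#' Write an epoch set to disk
#'
#' The on-disk container is a directory with a schema-versioned JSON header
#' (`header.json`: shapes, names, rates, labels, time axis) and a raw
#' little-endian float64 array (`data.bin`) laid out sample-fastest:
#' trial-major, then channel, then sample. Writers are deterministic —
#' identical inputs produce identical bytes.
#'
#' @param epochs an [epoch_set()].
#' @param path directory to create (must not be an existing non-empty file).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1L] < 2L || length(unique(epochs$labels)) < 2L)
    stop_dpifuse("refusing to write a degenerate epoch set (need >= 2 trials with both classes)",
                 "dpifuse_validation_error")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    schema_version = EPOCH_SCHEMA_VERSION,
    n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
    sampling_rate = epochs$sampling_rate,
    channel_names = epochs$channel_names,
    time_axis = epochs$time_axis,
    labels = epochs$labels,
    byte_order = "little", dtype = "float64",
    layout = "trial_channel_sample",
    metadata = epochs$metadata
  )
  json <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(path, "header.json"), useBytes = TRUE)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  # aperm so the sample index varies fastest within a trial
  writeBin(as.vector(aperm(epochs$data, c(3L, 2L, 1L))), con,
           size = 8L, endian = "little")
  invisible(path)
}

#' Read an epoch set from disk
#'
#' @param path a directory written by [write_epochs()].
#' @return an [epoch_set()]; a lossless round-trip of all fields.
#' @export
read_epochs <- function(path) {
  hpath <- file.path(path, "header.json")
  if (!file.exists(hpath))
    stop_dpifuse(sprintf("no epoch container at '%s' (header.json missing)", path),
                 "dpifuse_format_error")
  header <- jsonlite::fromJSON(hpath, simplifyVector = TRUE)
  if (!identical(header$schema_version, EPOCH_SCHEMA_VERSION))
    stop_dpifuse(sprintf("unsupported epoch container schema version '%s' (supported: %s)",
                         header$schema_version, EPOCH_SCHEMA_VERSION),
                 "dpifuse_format_error")
  n <- header$n_trials * header$n_channels * header$n_samples
  bpath <- file.path(path, "data.bin")
  sz <- file.info(bpath)$size
  if (is.na(sz) || sz != 8 * n)
    stop_dpifuse(sprintf(
      "header claims %d x %d x %d (%d bytes) but data.bin has %s bytes",
      header$n_trials, header$n_channels, header$n_samples, 8 * n,
      ifelse(is.na(sz), "no", format(sz))), "dpifuse_format_error")
  con <- file(bpath, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = n, size = 8L, endian = "little")
  data <- aperm(array(x, dim = c(header$n_samples, header$n_channels,
                                 header$n_trials)), c(3L, 2L, 1L))
  md <- header$metadata
  if (is.null(md) || length(md) == 0L) md <- list()
  epoch_set(data, header$labels, header$time_axis, header$channel_names,
            header$sampling_rate, md)
}

#' Read / write per-trial detector score tables
#'
#' Score tables are UTF-8, comma-delimited text with one header line and the
#' columns `trial_id,posterior,label`; posteriors use the `.` decimal
#' separator and round-trip losslessly to 12 significant digits.
#'
#' @param scores a [score_set()].
#' @param path file path of the CSV table.
#' @return `write_scores` returns `path` invisibly; `read_scores` returns a
#'   [score_set()] with rows in file order.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "score_set"))
  lines <- c("trial_id,posterior,label",
             sprintf("%s,%s,%d", as.character(scores$trial_ids),
                     formatC(scores$posteriors, format = "g", digits = 12),
                     scores$labels))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @param source_id source name to attach to the returned set.
#' @export
read_scores <- function(path, source_id = basename(path)) {
  df <- utils::read.csv(path, colClasses = c(trial_id = "character",
                                             posterior = "numeric",
                                             label = "integer"))
  req <- c("trial_id", "posterior", "label")
  if (!all(req %in% names(df)))
    stop_dpifuse(sprintf("score table must have columns %s",
                         paste(req, collapse = ", ")),
                 "dpifuse_format_error")
  bad <- which(!is.finite(df$posterior) | df$posterior < 0 | df$posterior > 1)
  if (length(bad))
    stop_dpifuse(sprintf("posterior outside [0,1] at row %d", bad[1L]),
                 "dpifuse_validation_error")
  if (anyDuplicated(df$trial_id))
    stop_dpifuse(sprintf("duplicate trial_id '%s'",
                         df$trial_id[anyDuplicated(df$trial_id)]),
                 "dpifuse_validation_error")
  score_set(df$posterior, df$label, trial_ids = df$trial_id,
            source_id = source_id)
}
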