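#' EEG recording container
#'
#' An `eeg_recording` holds a channel-major signal matrix in microvolts
#' together with its sampling rate, ordered channel names, subject metadata
#' and the raw clinical report text. This mirrors the reader contract for
#' EDF-style clinical EEG: all channels must share one sampling rate (readers
#' of formats that allow per-channel rates must resample to a common rate
#' before constructing the object), and amplitudes are physical microvolts.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz (positive scalar).
#' @param channel_names character vector, one name per signal row.
#' @param subject_meta list with elements `age` (integer years),
#'   `gender` (`"M"` or `"F"`) and `pathological` (logical). Missing elements
#'   are kept as `NA` rather than guessed.
#' @param report_text raw report string (possibly empty).
#' @param id optional recording identifier.
#'
#' @return an object of class `eeg_recording`.
#' @export
new_eeg_recording <- function(signal, rate, channel_names,
                              subject_meta = list(), report_text = "",
                              id = NULL) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be numeric")
  if (nrow(signal) != length(channel_names)) {
    stop("signal has ", nrow(signal), " rows but ", length(channel_names),
         " channel names were given")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar (Hz)")
  }
  meta <- list(
    age = if (is.null(subject_meta$age)) NA_integer_ else as.integer(subject_meta$age),
    gender = if (is.null(subject_meta$gender)) NA_character_ else as.character(subject_meta$gender),
    pathological = if (is.null(subject_meta$pathological)) NA else as.logical(subject_meta$pathological)
  )
  structure(
    list(signal = signal, rate = as.numeric(rate),
         channel_names = as.character(channel_names),
         subject_meta = meta, report_text = report_text, id = id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording%s: %d channels x %d samples @ %g Hz (%.1f s)>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              nrow(x$signal), ncol(x$signal), x$rate,
              ncol(x$signal) / x$rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$rate

#' Fixed-shape window batch
#'
#' A `window_set` is the model-ready product of preprocessing: an
#' `n x C x T` array of windows (default contract `C = 21` channels,
#' `T = 1200` samples at 100 Hz, i.e. 12 s), plus a length-`n` index of the
#' recording each window came from and the per-window start sample within
#' the preprocessed signal.
#'
#' @param windows numeric array `n x C x T`.
#' @param recording_ids length-`n` vector of recording identifiers.
#' @param rate sampling rate of the windows (Hz).
#' @param starts optional length-`n` integer vector of 0-based start samples.
#' @return an object of class `window_set`.
#' @export
new_window_set <- function(windows, recording_ids, rate = 100,
                           starts = NULL) {
  stopifnot(length(dim(windows)) == 3L)
  n <- dim(windows)[1]
  if (length(recording_ids) != n) stop("recording_ids must have one entry per window")
  structure(
    list(windows = windows, recording_ids = recording_ids,
         rate = rate, starts = starts),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set: %d windows of %d x %d @ %g Hz from %d recordings>\n",
              d[1], d[2], d[3], x$rate, length(unique(x$recording_ids))))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a `window_set`.
#' @return integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[1]

#' Write / read a recording as a plain-text container
#'
#' Text-based interchange format used in place of binary EDF: the signal is
#' stored as a CSV with one column per channel (values in microvolts), plus a
#' small JSON-free header line comment carrying rate and metadata. Intended
#' for small corpora and test fixtures; large corpora should stay in memory.
#'
#' @param rec an `eeg_recording`.
#' @param path file path.
#' @return `read_recording_csv` returns an `eeg_recording`;
#'   `write_recording_csv` returns `path` invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- rec$subject_meta
  writeLines(sprintf("# rate=%g age=%s gender=%s pathological=%s id=%s",
                     rec$rate, meta$age, meta$gender, meta$pathological,
                     if (is.null(rec$id)) "NA" else rec$id), con)
  utils::write.table(
    t(rec$signal), con, sep = ",", row.names = FALSE,
    col.names = rec$channel_names, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  fields <- regmatches(hdr, gregexpr("[a-z]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  new_eeg_recording(
    signal = t(as.matrix(df)),
    rate = as.numeric(vals[["rate"]]),
    channel_names = colnames(df),
    subject_meta = list(
      age = suppressWarnings(as.integer(vals[["age"]])),
      gender = if (vals[["gender"]] %in% c("M", "F")) vals[["gender"]] else NA_character_,
      pathological = if (vals[["pathological"]] %in% c("TRUE", "FALSE"))
        as.logical(vals[["pathological"]]) else NA
    ),
    id = if (identical(vals[["id"]], "NA")) NULL else vals[["id"]]
  )
}
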