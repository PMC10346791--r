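#' EEG recording objects
#'
#' An `eeg_recording` holds one multichannel EEG: a channels-by-samples signal
#' matrix in microvolts, its sampling rate, ordered channel labels, a subject
#' identifier and a recording-level class label (`"normal"`, `"abnormal"` or
#' `"unknown"`).
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of channel names, one per signal row.
#'   Labels are normalized with [normalize_label()] and must be unique
#'   afterwards.
#' @param subject_id opaque subject identifier string.
#' @param class_label one of `"normal"`, `"abnormal"`, `"unknown"`.
#'
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 100), 2), fs = 100,
#'                      labels = c("EEG FP1-REF", "EEG FP2-REF"))
#' rec$labels
#' @export
eeg_recording <- function(signal, fs, labels, subject_id = "anonymous",
                          class_label = c("unknown", "normal", "abnormal")) {
  class_label <- match.arg(class_label)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop_eegwave("`signal` must be a numeric channels-by-samples matrix",
                 "eegwave_invalid_recording")
  if (nrow(signal) == 0L)
    stop_eegwave("recording has zero channels", "eegwave_invalid_recording")
  if (!all(is.finite(signal)))
    stop_eegwave("recording contains non-finite samples",
                 "eegwave_invalid_recording")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_eegwave("`fs` must be a positive scalar", "eegwave_invalid_recording")
  labels <- vapply(as.character(labels), normalize_label, character(1),
                   USE.NAMES = FALSE)
  if (length(labels) != nrow(signal))
    stop_eegwave("number of labels must equal number of signal rows",
                 "eegwave_invalid_recording")
  if (anyDuplicated(labels))
    stop_eegwave(
      sprintf("duplicate channel labels after normalization: %s",
              paste(unique(labels[duplicated(labels)]), collapse = ", ")),
      "eegwave_invalid_recording")
  rownames(signal) <- labels
  structure(
    list(signal = signal, fs = as.numeric(fs), labels = labels,
         subject_id = as.character(subject_id), class_label = class_label),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), subject %s, label %s\n",
    nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs,
    x$subject_id, x$class_label))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [eeg_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$fs

# Modern 10-20 temporal/posterior names mapped to the legacy names used by
# clinical bipolar montages.
.label_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Normalize an EEG channel label
#'
#' Strips the `"EEG "` modality prefix and `"-REF"`/`"-LE"` reference
#' suffixes, trims whitespace, upper-cases, and maps the modern 10-20
#' temporal-chain names to their legacy equivalents (T7->T3, T8->T4, P7->T5,
#' P8->T6).  Unknown labels pass through normalized; missing electrodes are
#' flagged downstream by montage derivation.  The function is idempotent.
#'
#' @param raw a single raw channel label, e.g. `"EEG FP1-REF"`.
#' @return the canonical label, e.g. `"FP1"`.
#' @examples
#' normalize_label("EEG FP1-REF") # "FP1"
#' normalize_label("T7")          # "T3"
#' @export
normalize_label <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  x <- toupper(trimws(raw))
  x <- sub("^EEG\\s+", "", x)
  x <- sub("-(REF|LE)$", "", x)
  x <- trimws(x)
  if (x %in% names(.label_aliases)) x <- unname(.label_aliases[[x]])
  x
}

#' Read an EEG recording from file
#'
#' Currently supports 16-bit EDF.  Channel labels are normalized
#' ([normalize_label()]), the sampling rate is taken from the file header and
#' the signal is returned in microvolts using the EDF physical scaling.  The
#' class label is `"unknown"` unless supplied: recording-level labels live in
#' a sidecar manifest (see [read_manifest()]), not in the file.
#'
#' @param path path to the file.
#' @param fmt `"edf"` or `"autodetect"` (inspects the file, currently
#'   recognises EDF only).
#' @param class_label optional class label to attach.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, fmt = c("autodetect", "edf"),
                           class_label = c("unknown", "normal", "abnormal")) {
  fmt <- match.arg(fmt)
  class_label <- match.arg(class_label)
  if (!file.exists(path))
    stop_eegwave(sprintf("file not found: %s", path), "eegwave_format_error")
  if (fmt == "autodetect") {
    if (!is_edf_file(path))
      stop_eegwave(sprintf("cannot autodetect format of %s (not EDF)", path),
                   "eegwave_format_error")
    fmt <- "edf"
  }
  raw <- tryCatch(read_edf(path), error = function(e) {
    stop_eegwave(sprintf("failed to read %s as EDF: %s", path,
                         conditionMessage(e)), "eegwave_format_error")
  })
  eeg_recording(raw$signal, fs = raw$fs, labels = raw$labels,
                subject_id = raw$subject_id, class_label = class_label)
}

#' Read a label manifest
#'
#' A manifest is a CSV file with header `path,label`; `label` must be
#' `normal` or `abnormal`.  Relative paths are resolved against the manifest
#' directory.
#'
#' @param path path to the CSV manifest.
#' @return a data.frame with columns `path` and `label`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop_eegwave("manifest must have columns `path` and `label`",
                 "eegwave_format_error")
  if (!all(m$label %in% c("normal", "abnormal")))
    stop_eegwave("manifest labels must be 'normal' or 'abnormal'",
                 "eegwave_format_error")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}
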