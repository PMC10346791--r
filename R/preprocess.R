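#' Filter specifications
#'
#' Describes one of the three filters used by the clinical preprocessing
#' pipeline: a Butterworth high-pass, a Butterworth band-pass, or a
#' second-order IIR notch.  Filters are applied zero-phase
#' (forward-backward), so the effective magnitude response is the squared
#' single-pass response and no group delay is introduced.
#'
#' @param kind `"highpass"`, `"bandpass"` or `"notch"`.
#' @param cutoff_hz one cutoff (highpass, notch centre) or two (bandpass),
#'   in Hz.
#' @param order Butterworth order (ignored for notch).
#' @param notch_q dimensionless quality factor of the notch (centre
#'   frequency / -3 dB bandwidth).
#' @return a `filter_spec` object.
#' @examples
#' filter_spec("highpass", 1, order = 4)
#' filter_spec("notch", 60)
#' @export
filter_spec <- function(kind = c("highpass", "bandpass", "notch"),
                        cutoff_hz, order = 4L, notch_q = 30) {
  kind <- match.arg(kind)
  cutoff_hz <- as.numeric(cutoff_hz)
  n_needed <- if (kind == "bandpass") 2L else 1L
  if (length(cutoff_hz) != n_needed || any(cutoff_hz <= 0))
    stop_eegwave(sprintf("%s filter needs %d positive cutoff(s)", kind,
                         n_needed), "eegwave_parameter_error")
  if (kind == "bandpass" && cutoff_hz[1] >= cutoff_hz[2])
    stop_eegwave("bandpass low cutoff must be below high cutoff",
                 "eegwave_parameter_error")
  if (kind != "notch" && (!is_count(order) || order < 1))
    stop_eegwave("`order` must be a positive integer",
                 "eegwave_parameter_error")
  structure(list(kind = kind, cutoff_hz = cutoff_hz,
                 order = as.integer(order), notch_q = notch_q),
            class = "filter_spec")
}

# second-order (biquad) IIR notch, unit gain away from the centre frequency
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

filter_coefs <- function(spec, fs) {
  nyq <- fs / 2
  if (any(spec$cutoff_hz >= nyq))
    stop_eegwave(sprintf(
      "filter cutoff %g Hz must be below the Nyquist frequency %g Hz",
      max(spec$cutoff_hz), nyq), "eegwave_parameter_error")
  switch(spec$kind,
    highpass = {
      bt <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "high")
      list(b = bt$b, a = bt$a)
    },
    bandpass = {
      bt <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "pass")
      list(b = bt$b, a = bt$a)
    },
    notch = design_notch(spec$cutoff_hz, fs, spec$notch_q))
}

# steady-state filter state for a unit step input (the standard
# initial-condition construction that suppresses start-up transients)
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  bb <- c(b, numeric(nf - length(b))) / a[1]
  aa <- c(a, numeric(nf - length(a))) / a[1]
  n <- nf - 1L
  A <- rbind(-aa[-1], cbind(diag(1, n - 1L), 0))
  B <- bb[-1] - aa[-1] * bb[1]
  solve(diag(n) - t(A), B)
}

# zero-phase filtering: odd-reflection padding at both ends plus scaled
# steady-state initial conditions, applied forward then backward
filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  edge <- 3L * max(length(a), length(b))
  if (n <= edge)
    stop_eegwave("signal too short for zero-phase filtering",
                 "eegwave_parameter_error")
  ext <- c(2 * x[1] - x[(edge + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - edge)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(edge + 1L):(edge + n)]
}

#' Zero-phase filtering of a recording
#'
#' Applies the filter independently to every channel, forward and backward
#' with odd-reflection edge padding and steady-state initial conditions, so
#' no group delay and no start-up transient are introduced; length and
#' sampling rate are preserved.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [filter_spec()].
#' @return the filtered [eeg_recording()].
#' @export
apply_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  co <- filter_coefs(spec, rec$fs)
  out <- t(apply(rec$signal, 1L, function(x) filtfilt_zp(co$b, co$a, x)))
  rec$signal <- out
  rownames(rec$signal) <- rec$labels
  rec
}

# The 20-channel TCP (temporal central parasagittal) bipolar montage:
# the standard TUH TCP chain set with the ear-reference chains omitted.
.tcp20_pairs <- matrix(c(
  "FP1", "F7",  "F7", "T3",  "T3", "T5",  "T5", "O1",
  "FP2", "F8",  "F8", "T4",  "T4", "T6",  "T6", "O2",
  "T3",  "C3",  "C3", "CZ",  "CZ", "C4",  "C4", "T4",
  "FP1", "F3",  "F3", "C3",  "C3", "P3",  "P3", "O1",
  "FP2", "F4",  "F4", "C4",  "C4", "P4",  "P4", "O2"),
  ncol = 2L, byrow = TRUE)

#' Bipolar montage specifications
#'
#' A montage is an ordered list of (anode, cathode) electrode pairs; deriving
#' it replaces the referential channels by anode-minus-cathode differences.
#' `tcp_montage_20()` returns the 20-channel TCP montage used for clinical
#' abnormality screening, which accentuates focal spike activity.
#'
#' @param pairs two-column character matrix of (anode, cathode) names.
#' @param name montage name.
#' @return a `montage_spec` object.
#' @export
montage_spec <- function(pairs, name = "custom") {
  stopifnot(is.matrix(pairs), ncol(pairs) == 2L)
  pairs[] <- vapply(pairs, normalize_label, character(1))
  key <- paste(pairs[, 1L], pairs[, 2L], sep = "-")
  if (anyDuplicated(key))
    stop_eegwave("montage pairs must be unique", "eegwave_parameter_error")
  structure(list(pairs = pairs, name = name), class = "montage_spec")
}

#' @rdname montage_spec
#' @export
tcp_montage_20 <- function() montage_spec(.tcp20_pairs, name = "tcp20")

#' Derive a bipolar montage
#'
#' Output channel i is the sample-wise difference anode_i - cathode_i; output
#' labels are `"ANODE-CATHODE"` strings in montage order.
#'
#' @param rec an [eeg_recording()] containing every electrode named by the
#'   montage.
#' @param spec a [montage_spec()]; defaults to [tcp_montage_20()].
#' @return an [eeg_recording()] with `nrow(spec$pairs)` channels.
#' @export
derive_tcp_montage <- function(rec, spec = tcp_montage_20()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "montage_spec"))
  needed <- unique(c(spec$pairs))
  missing <- setdiff(needed, rec$labels)
  if (length(missing) > 0L)
    stop_eegwave(sprintf("montage %s requires missing electrode(s): %s",
                         spec$name, paste(sort(missing), collapse = ", ")),
                 "eegwave_missing_electrodes")
  out <- rec$signal[spec$pairs[, 1L], , drop = FALSE] -
         rec$signal[spec$pairs[, 2L], , drop = FALSE]
  labels <- paste(spec$pairs[, 1L], spec$pairs[, 2L], sep = "-")
  rec$signal <- out
  rec$labels <- labels
  rownames(rec$signal) <- labels
  rec
}

#' Resample a recording
#'
#' Band-limited polyphase resampling (`signal::resample`) to `target_fs`;
#' output length is `round(n * target_fs / fs)`.  When `target_fs` equals the
#' current rate the signal is returned unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate in Hz.
#' @return the resampled [eeg_recording()].
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop_eegwave("`target_fs` must be a positive scalar",
                 "eegwave_parameter_error")
  if (target_fs == rec$fs) return(rec)
  n <- ncol(rec$signal)
  len_out <- round(n * target_fs / rec$fs)
  frac <- rational_ratio(target_fs, rec$fs)
  out <- matrix(0, nrow = nrow(rec$signal), ncol = len_out)
  for (i in seq_len(nrow(out))) {
    y <- signal::resample(rec$signal[i, ], p = frac[1L], q = frac[2L])
    if (length(y) >= len_out) out[i, ] <- y[seq_len(len_out)]
    else out[i, seq_along(y)] <- y
  }
  rec$signal <- out
  rownames(rec$signal) <- rec$labels
  rec$fs <- target_fs
  rec
}

# small-denominator rational approximation of p/q for polyphase resampling
rational_ratio <- function(p, q) {
  if (p == round(p) && q == round(q)) {
    g <- gcd_int(round(p), round(q))
    return(c(round(p) / g, round(q) / g))
  }
  r <- p / q
  best <- c(1L, 1L)
  for (den in 1:1000) {
    num <- round(r * den)
    if (num >= 1 && abs(num / den - r) < 1e-9) { best <- c(num, den); break }
  }
  best
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Segment sets
#'
#' A `segment_set` holds fixed-length model-ready segments: a numeric array
#' `data` of shape (n_segments, channels, samples), per-segment class
#' `labels`, per-segment `provenance` (`"original"` or `"reversed"`),
#' per-segment source `recording_id`, the sampling rate and the channel
#' names.
#'
#' @param data numeric array (n_segments x channels x samples).
#' @param labels character vector of per-segment class labels.
#' @param fs sampling rate in Hz.
#' @param provenance character vector, `"original"`/`"reversed"`.
#' @param channel_names channel names (length = dim 2 of data).
#' @param recording_id per-segment source recording identifier.
#' @return a `segment_set` object.
#' @export
segment_set <- function(data, labels, fs, provenance, channel_names,
                        recording_id = rep(NA_character_, dim(data)[1L])) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n <- dim(data)[1L]
  stopifnot(length(labels) == n, length(provenance) == n,
            length(recording_id) == n,
            length(channel_names) == dim(data)[2L])
  structure(list(data = data, labels = as.character(labels), fs = fs,
                 provenance = as.character(provenance),
                 channel_names = as.character(channel_names),
                 recording_id = as.character(recording_id)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<segment_set> %d segments x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 table(x$labels)), collapse = " "),
      " provenance:", paste(sprintf("%s=%d", names(table(x$provenance)),
                                    table(x$provenance)), collapse = " "),
      "\n")
  invisible(x)
}

#' Number of segments in a segment set
#' @param segs a [segment_set()].
#' @return integer count.
#' @export
n_segments <- function(segs) dim(segs$data)[1L]

#' Combine segment sets
#' @param ... [segment_set()] objects with identical channel layout and fs.
#' @return the concatenated [segment_set()].
#' @export
bind_segments <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "segment_set")) sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1L]]
  for (s in sets[-1L])
    stopifnot(identical(s$channel_names, ref$channel_names), s$fs == ref$fs,
              identical(dim(s$data)[2:3], dim(ref$data)[2:3]))
  n <- sum(vapply(sets, n_segments, integer(1)))
  d <- dim(ref$data)
  data <- array(0, c(n, d[2L], d[3L]))
  at <- 0L
  for (s in sets) {
    k <- n_segments(s)
    if (k > 0L) data[at + seq_len(k), , ] <- s$data
    at <- at + k
  }
  segment_set(data,
              labels = unlist(lapply(sets, `[[`, "labels")),
              fs = ref$fs,
              provenance = unlist(lapply(sets, `[[`, "provenance")),
              channel_names = ref$channel_names,
              recording_id = unlist(lapply(sets, `[[`, "recording_id")))
}

#' Subset a segment set
#' @param segs a [segment_set()].
#' @param idx integer or logical index over segments.
#' @return the subset [segment_set()].
#' @export
subset_segments <- function(segs, idx) {
  segment_set(segs$data[idx, , , drop = FALSE], segs$labels[idx], segs$fs,
              segs$provenance[idx], segs$channel_names, segs$recording_id[idx])
}

#' Extract fixed-length segments with time-reverse augmentation
#'
#' Segment 1 is the first `seg_seconds` of the recording (provenance
#' `"original"`).  With `augment_reverse = TRUE` and at least
#' `2 * seg_seconds` of signal, the second `seg_seconds` window is added in
#' reverse time order (provenance `"reversed"`) - time-reverse augmentation.
#' Labels are inherited from the recording.
#'
#' @param rec an [eeg_recording()] of duration >= `seg_seconds`.
#' @param seg_seconds segment length in seconds.
#' @param augment_reverse add the reversed second window when available.
#' @return a [segment_set()] with 1 or 2 segments.
#' @export
extract_segments <- function(rec, seg_seconds = 60, augment_reverse = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- as.integer(round(seg_seconds * rec$fs))
  n <- ncol(rec$signal)
  if (n < L)
    stop_eegwave(sprintf(
      "recording too short: %.2f s available, %.2f s required",
      n / rec$fs, seg_seconds), "eegwave_too_short",
      duration = n / rec$fs)
  segs <- list(rec$signal[, 1:L, drop = FALSE])
  prov <- "original"
  if (isTRUE(augment_reverse) && n >= 2L * L) {
    second <- rec$signal[, (L + 1L):(2L * L), drop = FALSE]
    segs <- c(segs, list(second[, L:1, drop = FALSE]))
    prov <- c(prov, "reversed")
  }
  data <- array(0, c(length(segs), nrow(rec$signal), L))
  for (i in seq_along(segs)) data[i, , ] <- segs[[i]]
  segment_set(data, labels = rep(rec$class_label, length(segs)), fs = rec$fs,
              provenance = prov, channel_names = rec$labels,
              recording_id = rep(rec$subject_id, length(segs)))
}

#' Standardize segments per channel
#'
#' For every segment and channel independently, subtracts the mean and
#' divides by the standard deviation (population denominator n).  A channel
#' with zero variance is left mean-centred with a unit denominator and a
#' warning, avoiding division by zero.
#'
#' @param segs a [segment_set()].
#' @return the standardized [segment_set()].
#' @export
standardize <- function(segs) {
  stopifnot(inherits(segs, "segment_set"))
  d <- dim(segs$data)
  warned <- FALSE
  for (i in seq_len(d[1L])) {
    x <- segs$data[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = d[2L])
    mu <- rowMeans(x)
    sdv <- sqrt(rowMeans((x - mu)^2))
    zero <- sdv < .Machine$double.eps
    if (any(zero)) warned <- TRUE
    sdv[zero] <- 1
    segs$data[i, , ] <- (x - mu) / sdv
  }
  if (warned)
    warning("zero-variance channel(s): standardized with unit denominator",
            call. = FALSE)
  segs
}

#' Run a named preprocessing profile
#'
#' `"tuab"` (abnormality screening): 4th-order Butterworth high-pass at
#' 1 Hz, 60 Hz notch, TCP-20 bipolar montage, resample to 250 Hz,
#' `seg_seconds` segments (default 60 s) with time-reverse augmentation,
#' per-channel standardization.
#'
#' `"tuep"` (epilepsy screening): 2nd-order Butterworth band-pass
#' 0.5-49 Hz, selection of the first 30 channels, resample to 250 Hz, first
#' `seg_seconds` (default 30 s) only with no augmentation, per-channel
#' standardization.
#'
#' @param rec an [eeg_recording()].
#' @param profile `"tuab"` or `"tuep"`.
#' @param seg_seconds segment length override in seconds (default 60 for
#'   `"tuab"`, 30 for `"tuep"`); shorter segments give proportionally
#'   smaller model inputs.
#' @param target_fs resampling target in Hz (default 250).
#' @return a standardized [segment_set()].
#' @export
preprocess_pipeline <- function(rec, profile = c("tuab", "tuep"),
                                seg_seconds = NULL, target_fs = 250) {
  profile <- match.arg(profile)
  if (profile == "tuab") {
    seg_seconds <- seg_seconds %||% 60
    rec <- apply_filter(rec, filter_spec("highpass", 1, order = 4L))
    rec <- apply_filter(rec, filter_spec("notch", 60))
    rec <- derive_tcp_montage(rec, tcp_montage_20())
    rec <- resample_recording(rec, target_fs)
    segs <- extract_segments(rec, seg_seconds, augment_reverse = TRUE)
  } else {
    seg_seconds <- seg_seconds %||% 30
    rec <- apply_filter(rec, filter_spec("bandpass", c(0.5, 49), order = 2L))
    if (nrow(rec$signal) < 30L)
      stop_eegwave(sprintf(
        "tuep profile needs at least 30 channels, got %d", nrow(rec$signal)),
        "eegwave_parameter_error")
    rec$signal <- rec$signal[1:30, , drop = FALSE]
    rec$labels <- rec$labels[1:30]
    rec <- resample_recording(rec, target_fs)
    segs <- extract_segments(rec, seg_seconds, augment_reverse = FALSE)
  }
  standardize(segs)
}

#' Preprocess every recording of a manifest or list
#'
#' @param recs list of [eeg_recording()] objects.
#' @param profile,seg_seconds,target_fs passed to [preprocess_pipeline()].
#' @return one combined [segment_set()].
#' @export
preprocess_recordings <- function(recs, profile = "tuab", seg_seconds = NULL,
                                  target_fs = 250) {
  sets <- lapply(recs, preprocess_pipeline, profile = profile,
                 seg_seconds = seg_seconds, target_fs = target_fs)
  bind_segments(sets)
}
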