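# Minimal 16-bit EDF input/output.
#
# EDF stores an ASCII header (256 bytes + 256 per signal, field-major) and
# little-endian int16 data records; physical values are recovered by linear
# scaling between the digital and physical ranges declared per signal.  Only
# the plain-EDF subset needed for clinical EEG is handled: equal sampling
# rate across signals, no annotation channels.

is_edf_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 8L)
  length(hdr) == 8L && identical(rawToChar(hdr), "0       ")
}

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

read_ascii_vec <- function(con, ns, width)
  vapply(seq_len(ns), function(i) read_ascii(con, width), character(1))

# Returns list(signal, fs, labels, subject_id); signal in physical units.
read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  version <- read_ascii(con, 8L)
  if (version != "0") stop("not an EDF file (bad version field)")
  patient <- read_ascii(con, 80L)
  read_ascii(con, 80L)                      # recording id
  read_ascii(con, 8L); read_ascii(con, 8L)  # start date, time
  read_ascii(con, 8L)                       # header bytes
  read_ascii(con, 44L)                      # reserved
  n_records <- as.integer(read_ascii(con, 8L))
  rec_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("EDF header declares zero signals")
  labels <- read_ascii_vec(con, ns, 16L)
  read_ascii_vec(con, ns, 80L)              # transducer
  read_ascii_vec(con, ns, 8L)               # physical dimension
  pmin <- as.numeric(read_ascii_vec(con, ns, 8L))
  pmax <- as.numeric(read_ascii_vec(con, ns, 8L))
  dmin <- as.numeric(read_ascii_vec(con, ns, 8L))
  dmax <- as.numeric(read_ascii_vec(con, ns, 8L))
  read_ascii_vec(con, ns, 80L)              # prefiltering
  nr <- as.integer(read_ascii_vec(con, ns, 8L))
  read_ascii_vec(con, ns, 32L)              # reserved
  if (length(unique(nr / rec_dur)) != 1L)
    stop("signals with differing sampling rates are not supported")
  if (any(is.na(c(pmin, pmax, dmin, dmax, nr))))
    stop("malformed EDF signal headers")
  fs <- nr[1L] / rec_dur
  n_total <- n_records * nr[1L]
  signal <- matrix(0, nrow = ns, ncol = n_total)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", nr[s], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) != nr[s]) stop("truncated EDF data record")
      signal[s, ((r - 1L) * nr[s] + 1L):(r * nr[s])] <-
        (d - dmin[s]) * scale[s] + pmin[s]
    }
  }
  list(signal = signal, fs = fs, labels = labels,
       subject_id = if (nzchar(patient)) patient else "anonymous")
}

pad_ascii <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

fmt_num8 <- function(x) {
  vapply(x, function(v) {
    s <- formatC(v, digits = 6, format = "g")
    if (nchar(s) > 8L) s <- formatC(v, digits = 3, format = "g")
    pad_ascii(s, 8L)
  }, character(1))
}

#' Write a recording to 16-bit EDF
#'
#' Writes one EDF file with per-channel physical scaling spanning the channel
#' range, digital range -32768..32767.  The record duration is 1 s when the
#' sample count divides evenly by `fs`, otherwise the whole signal is written
#' as a single record.  Quantization error is bounded by half a digital step
#' of the per-channel physical range.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sig <- rec$signal
  ns <- nrow(sig); n <- ncol(sig)
  if (n %% rec$fs == 0 && rec$fs == round(rec$fs)) {
    nr <- as.integer(rec$fs); rec_dur <- 1
  } else {
    nr <- n; rec_dur <- n / rec$fs
  }
  n_records <- n %/% nr
  pmin <- apply(sig, 1L, min); pmax <- apply(sig, 1L, max)
  flat <- pmax - pmin < 1e-9
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  wrt <- function(x, width) writeBin(charToRaw(pad_ascii(x, width)), con)
  wrt("0", 8L)
  wrt(rec$subject_id, 80L)
  wrt("eegwave", 80L)
  wrt("01.01.00", 8L); wrt("00.00.00", 8L)
  wrt(as.character(256L + 256L * ns), 8L)
  wrt("", 44L)
  wrt(as.character(n_records), 8L)
  wrt(format(rec_dur, digits = 6), 8L)
  wrt(as.character(ns), 4L)
  for (lab in rec$labels) wrt(paste0("EEG ", lab, "-REF"), 16L)
  for (i in seq_len(ns)) wrt("AgAgCl electrode", 80L)
  for (i in seq_len(ns)) wrt("uV", 8L)
  for (i in seq_len(ns)) writeBin(charToRaw(fmt_num8(pmin[i])), con)
  for (i in seq_len(ns)) writeBin(charToRaw(fmt_num8(pmax[i])), con)
  for (i in seq_len(ns)) wrt(as.character(dmin), 8L)
  for (i in seq_len(ns)) wrt(as.character(dmax), 8L)
  for (i in seq_len(ns)) wrt("", 80L)
  for (i in seq_len(ns)) wrt(as.character(nr), 8L)
  for (i in seq_len(ns)) wrt("", 32L)
  # reuse the header's (possibly rounded) physical bounds so that reading
  # inverts writing exactly up to quantization
  pmin_h <- as.numeric(trimws(fmt_num8(pmin)))
  pmax_h <- as.numeric(trimws(fmt_num8(pmax)))
  scale <- (dmax - dmin) / (pmax_h - pmin_h)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * nr + 1L):(r * nr)
    for (s in seq_len(ns)) {
      d <- round((sig[s, idx] - pmin_h[s]) * scale[s] + dmin)
      d <- pmin(pmax(d, dmin), dmax)
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
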