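#' Synthetic EEG generator specification
#'
#' Parameters of the labelled synthetic EEG generator.  Normal recordings are
#' sums of band-limited filtered Gaussian noise shaped to a target relative
#' band-power profile, with a posterior-dominant alpha rhythm.  Abnormal
#' recordings additionally carry Poisson-timed ~3 Hz spike-and-wave bursts
#' (1-3 s, focal or generalized), diffuse slowing (a multiplicative boost of
#' the delta/theta components) and a left/right amplitude asymmetry - three
#' cardinal abnormality signatures a clinical reader looks for.
#'
#' Default values describe the study conditions used throughout the package:
#' 21 standard 10-20 electrodes, 130 s at 250 Hz (long enough for two 60-s
#' windows plus filter settling), discharge rate 6 bursts/min at 3 Hz,
#' slowing gain 2, asymmetry 0.7, background scale ~10 uV per band unit with
#' 2 uV broadband sensor noise.
#'
#' @param n_recordings number of recordings.
#' @param abnormal_fraction fraction in `[0, 1]` of abnormal recordings.
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds (`duration * fs` integral).
#' @param electrodes canonical 10-20 electrode names (>= 21 for the TCP
#'   montage profile).
#' @param background_band_power named relative power of the delta (1-4 Hz),
#'   theta (4-8), alpha (8-13) and beta (13-30) background components.
#' @param discharge_rate expected spike-wave bursts per minute (abnormal).
#' @param discharge_freq spike-wave repetition frequency, Hz.
#' @param slowing_gain multiplicative delta/theta boost (abnormal).
#' @param asymmetry left/right amplitude ratio (abnormal).
#' @param noise_sd broadband sensor noise, uV.
#' @param seed master seed; recording `index` uses stream `seed + index`, so
#'   a recording is independent of `n_recordings`.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_recordings = 120L,
                           abnormal_fraction = 0.5,
                           fs = 250,
                           duration = 130,
                           electrodes = standard_1020_21(),
                           background_band_power = c(delta = 1, theta = 0.8,
                                                     alpha = 1.2, beta = 0.6),
                           discharge_rate = 6,
                           discharge_freq = 3,
                           slowing_gain = 2,
                           asymmetry = 0.7,
                           noise_sd = 2,
                           seed = 1L) {
  stopifnot(is_count(n_recordings),
            abnormal_fraction >= 0, abnormal_fraction <= 1,
            fs > 0, duration > 0,
            abs(duration * fs - round(duration * fs)) < 1e-9,
            discharge_rate >= 0, discharge_freq > 0,
            all(background_band_power >= 0),
            all(c("delta", "theta", "alpha", "beta") %in%
                  names(background_band_power)),
            slowing_gain > 0, asymmetry > 0, noise_sd >= 0)
  electrodes <- vapply(electrodes, normalize_label, character(1),
                       USE.NAMES = FALSE)
  structure(list(n_recordings = as.integer(n_recordings),
                 abnormal_fraction = abnormal_fraction, fs = fs,
                 duration = duration, electrodes = electrodes,
                 background_band_power = background_band_power,
                 discharge_rate = discharge_rate,
                 discharge_freq = discharge_freq,
                 slowing_gain = slowing_gain, asymmetry = asymmetry,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Standard electrode sets
#'
#' `standard_1020_21()` returns the 21 electrodes of the classic 10-20
#' montage (legacy temporal names); `standard_1020_30()` an extended 30-name
#' set for the 30-channel epilepsy-screening profile.
#' @return character vector of electrode names.
#' @export
standard_1020_21 <- function() c(
  "FP1", "FP2", "F7", "F3", "FZ", "F4", "F8", "A1", "T3", "C3", "CZ", "C4",
  "T4", "A2", "T5", "P3", "PZ", "P4", "T6", "O1", "O2")

#' @rdname standard_1020_21
#' @export
standard_1020_30 <- function() c(
  standard_1020_21(),
  "FPZ", "OZ", "F9", "F10", "T9", "T10", "P9", "P10", "AFZ")

.band_edges <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                    beta = c(13, 30))
.posterior <- c("O1", "O2", "P3", "P4", "PZ", "T5", "T6")
.left_side <- c("FP1", "F7", "F3", "A1", "T3", "C3", "T5", "P3", "O1", "F9",
                "T9", "P9")

band_noise <- function(n, fs, band) {
  bt <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bt$b, bt$a, stats::rnorm(n))
  x / stats::sd(x)
}

spike_wave_kernel <- function(fs, freq, dur) {
  # one cycle = sharp biphasic spike (~70 ms) + slow half-sine "wave"
  cyc <- round(fs / freq)
  n_sp <- max(3L, round(0.07 * fs))
  spike <- c(seq(0, 1, length.out = ceiling(n_sp / 2)),
             seq(1, -0.4, length.out = n_sp - ceiling(n_sp / 2)))
  wave <- 0.8 * sin(pi * seq(0, 1, length.out = cyc - n_sp))
  one <- c(spike, wave)
  n_cycles <- max(1L, round(dur * freq))
  k <- rep(one, n_cycles)
  # taper the burst envelope so onsets are not step discontinuities
  k * signal::hanning(length(k))^0.25
}

#' Simulate one labelled EEG recording
#'
#' Deterministic given `(spec$seed, index, label)`.  Returns an
#' [eeg_recording()]; the ground-truth event log (burst start/end seconds and
#' affected channels, empty for normal recordings) is attached as attribute
#' `"events"`.
#'
#' @param spec a [synthetic_spec()].
#' @param label `"normal"` or `"abnormal"`.
#' @param index recording index (seed offset).
#' @return an [eeg_recording()] with attribute `"events"`.
#' @export
simulate_recording <- function(spec, label = c("normal", "abnormal"),
                               index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  label <- match.arg(label)
  n <- as.integer(round(spec$duration * spec$fs))
  ch <- spec$electrodes
  C <- length(ch)
  with_seed(spec$seed + as.integer(index), {
    bp <- spec$background_band_power
    if (label == "abnormal") {
      bp[c("delta", "theta")] <- bp[c("delta", "theta")] * spec$slowing_gain
    }
    base_uv <- 10
    sig <- matrix(0, C, n)
    for (i in seq_len(C)) {
      for (b in names(.band_edges)) {
        amp <- base_uv * sqrt(bp[[b]])
        if (b == "alpha" && ch[i] %in% .posterior) amp <- amp * 2
        sig[i, ] <- sig[i, ] + amp * band_noise(n, spec$fs, .band_edges[[b]])
      }
      sig[i, ] <- sig[i, ] + spec$noise_sd * stats::rnorm(n)
    }
    events <- data.frame(start = numeric(0), end = numeric(0),
                         channels = character(0))
    if (label == "abnormal") {
      # amplitude asymmetry: scale one hemisphere
      left <- ch %in% .left_side
      sig[left, ] <- sig[left, ] * spec$asymmetry
      # Poisson-timed spike-wave bursts
      n_bursts <- stats::rpois(1L, spec$discharge_rate * spec$duration / 60)
      focal <- stats::runif(1L) < 0.5
      aff <- if (focal) {
        hemi <- if (stats::runif(1L) < 0.5) c("F7", "T3", "T5", "FP1", "C3")
                else c("F8", "T4", "T6", "FP2", "C4")
        intersect(hemi, ch)
      } else ch
      aff_idx <- match(aff, ch)
      rms <- sqrt(rowMeans(sig[aff_idx, , drop = FALSE]^2))
      for (k in seq_len(n_bursts)) {
        dur <- stats::runif(1L, 1, 3)
        kern <- spike_wave_kernel(spec$fs, spec$discharge_freq, dur)
        if (length(kern) > n) kern <- kern[seq_len(n)]  # short recordings
        start <- sample.int(n - length(kern) + 1L, 1L)
        idx <- start:(start + length(kern) - 1L)
        # burst RMS = 3x the affected channel's background RMS
        amp <- 3 / sqrt(mean(kern^2))
        for (j in seq_along(aff_idx)) {
          sig[aff_idx[j], idx] <- sig[aff_idx[j], idx] + amp * rms[j] * kern
        }
        events <- rbind(events, data.frame(
          start = (start - 1L) / spec$fs,
          end = (start - 1L + length(kern)) / spec$fs,
          channels = paste(aff, collapse = ";")))
      }
    }
    rec <- eeg_recording(sig, fs = spec$fs, labels = ch,
                         subject_id = sprintf("sim-%04d", as.integer(index)),
                         class_label = label)
    attr(rec, "events") <- events
    rec
  })
}

#' Simulate a labelled dataset
#'
#' Generates `round(n_recordings * abnormal_fraction)` abnormal recordings
#' and normal recordings for the remainder, in interleaved index order, with
#' a manifest data frame mapping recording ids to labels.  Fully reproducible
#' from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `recordings` (list of [eeg_recording()]),
#'   `manifest` (data.frame: `id`, `label`) and `events` (list of per-
#'   recording event logs).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_recordings == 0L)
    stop_eegwave("cannot simulate an empty dataset (n_recordings = 0)",
                 "eegwave_empty_dataset")
  n_ab <- round(spec$n_recordings * spec$abnormal_fraction)
  # deterministic label layout: abnormal recordings take odd indices first,
  # so the two classes interleave regardless of the fraction
  ord <- c(seq(1L, spec$n_recordings, by = 2L),
           seq.int(2L, length.out = spec$n_recordings %/% 2L, by = 2L))
  labels <- rep("normal", spec$n_recordings)
  labels[ord[seq_len(n_ab)]] <- "abnormal"
  recs <- vector("list", spec$n_recordings)
  events <- vector("list", spec$n_recordings)
  for (i in seq_len(spec$n_recordings)) {
    recs[[i]] <- simulate_recording(spec, labels[i], index = i)
    events[[i]] <- attr(recs[[i]], "events")
  }
  manifest <- data.frame(
    id = vapply(recs, `[[`, character(1), "subject_id"),
    label = labels, stringsAsFactors = FALSE)
  list(recordings = recs, manifest = manifest, events = events)
}
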