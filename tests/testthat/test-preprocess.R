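# transfer-function oracle: |H(f)| of a rational filter evaluated on the
# unit circle, independent of the filtering code path
freq_gain <- function(b, a, f, fs) {
  z <- exp(-2i * pi * f / fs)
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}

steady <- function(x, fs, trim_s = 2) x[(trim_s * fs):(length(x) - trim_s * fs)]

test_that("high-pass filter removes DC and passes 10 Hz within the Butterworth oracle", {
  fs <- 250
  const <- eeg_recording(matrix(100, 1, fs * 10), fs, "FP1")
  hp <- filter_spec("highpass", 1, order = 4)
  out <- apply_filter(const, hp)
  expect_lt(max(abs(steady(out$signal[1, ], fs))), 100 * 1e-6)

  t <- seq_len(fs * 12) / fs
  sine <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs, "FP1")
  out <- apply_filter(sine, hp)
  got <- rms(steady(out$signal[1, ], fs))
  # analytic zero-phase gain: |H(10)|^2 = 1/(1 + (1/10)^8)
  expect_equal(got / rms(steady(sine$signal[1, ], fs)),
               1 / (1 + (1 / 10)^8), tolerance = 0.01)
})

test_that("60 Hz notch attenuates the mains line per its transfer function", {
  fs <- 250
  t <- seq_len(fs * 12) / fs
  sine <- eeg_recording(matrix(sin(2 * pi * 60 * t), 1), fs, "FP1")
  spec <- filter_spec("notch", 60)
  out <- apply_filter(sine, spec)
  expect_lt(rms(steady(out$signal[1, ], fs)) / rms(sine$signal[1, ]), 0.05)
  # the designed filter itself must already kill 60 Hz (squared when
  # applied forward-backward)
  co <- eegwave:::filter_coefs(spec, fs)
  expect_lt(freq_gain(co$b, co$a, 60, fs)^2, 0.0025)
  expect_gt(freq_gain(co$b, co$a, 10, fs)^2, 0.99)
})

test_that("filter cutoffs at or above Nyquist are rejected by name", {
  rec <- toy_recording(fs = 100, seconds = 2)
  err <- expect_error(apply_filter(rec, filter_spec("highpass", 60)),
                      class = "eegwave_parameter_error")
  expect_match(conditionMessage(err), "60")
  expect_error(filter_spec("bandpass", c(30, 10)),
               class = "eegwave_parameter_error")
})

test_that("zero-phase filtering leaves a band-limited pulse unshifted", {
  fs <- 250
  n <- fs * 8
  x <- numeric(n)
  t <- seq(-1, 1, length.out = fs)
  x[(n / 2):(n / 2 + fs - 1)] <- exp(-t^2 / 0.02) * cos(2 * pi * 8 * t)
  rec <- eeg_recording(matrix(x, 1), fs, "CZ")
  out <- apply_filter(rec, filter_spec("highpass", 1, order = 4))
  cc <- stats::ccf(out$signal[1, ], x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("TCP-20 montage derives 20 anode-minus-cathode channels", {
  rec <- toy_recording()
  out <- derive_tcp_montage(rec)
  expect_equal(nrow(out$signal), 20L)
  expect_equal(out$labels[1], "FP1-F7")
  expect_equal(out$signal[1, ],
               unname(rec$signal["FP1", ] - rec$signal["F7", ]))
  expect_equal(out$signal["C3-CZ", ],
               unname(rec$signal["C3", ] - rec$signal["CZ", ]))

  same <- eeg_recording(matrix(rep(sin(1:100), 21), 21, byrow = TRUE),
                        250, standard_1020_21())
  zero <- derive_tcp_montage(same)
  expect_true(all(zero$signal == 0))
})

test_that("montage reports all missing electrodes", {
  rec <- toy_recording()
  keep <- !(rec$labels %in% c("T3", "O2"))
  sub <- eeg_recording(rec$signal[keep, ], rec$fs, rec$labels[keep])
  err <- expect_error(derive_tcp_montage(sub),
                      class = "eegwave_missing_electrodes")
  expect_match(conditionMessage(err), "T3")
  expect_match(conditionMessage(err), "O2")
})

test_that("montage is linear and commutes with filtering", {
  f <- with_test_seed(11, toy_recording(seed = 11))
  g <- with_test_seed(12, toy_recording(seed = 12))
  a <- 2.5; b <- -1.25
  mix <- eeg_recording(a * f$signal + b * g$signal, f$fs, f$labels)
  lhs <- derive_tcp_montage(mix)$signal
  rhs <- a * derive_tcp_montage(f)$signal + b * derive_tcp_montage(g)$signal
  expect_equal(lhs, rhs, tolerance = 1e-12)

  spec <- filter_spec("highpass", 1, order = 4)
  m_then_f <- apply_filter(derive_tcp_montage(f), spec)$signal
  f_then_m <- derive_tcp_montage(apply_filter(f, spec))$signal
  expect_lt(max(abs(m_then_f - f_then_m)) / max(abs(m_then_f)), 1e-8)
})

test_that("resampling follows the rounding rule, identity and spectrum", {
  rec <- toy_recording(fs = 500, seconds = 10)  # 5000 samples
  down <- resample_recording(rec, 250)
  expect_equal(ncol(down$signal), 2500L)
  expect_equal(down$fs, 250)

  same <- resample_recording(rec, 500)
  expect_identical(same$signal, rec$signal)

  half <- resample_recording(down, 125)
  expect_equal(ncol(half$signal), 1250L)

  fs <- 1000
  t <- seq_len(fs * 4) / fs
  sine <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs, "O1")
  out <- resample_recording(sine, 250)
  sp <- stats::spec.pgram(stats::ts(out$signal[1, ], frequency = 250),
                          taper = 0, plot = FALSE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 10), 0.5)
})

test_that("segmentation takes the first window and reverses the second", {
  rec <- toy_recording(fs = 250, seconds = 130, label = "abnormal")
  segs <- extract_segments(rec, 60, augment_reverse = TRUE)
  expect_equal(dim(segs$data), c(2L, 21L, 15000L))
  expect_identical(segs$provenance, c("original", "reversed"))
  expect_identical(segs$labels, c("abnormal", "abnormal"))
  expect_equal(segs$data[1, , ], unname(rec$signal[, 1:15000]))
  second <- rec$signal[, 15001:30000]
  expect_equal(segs$data[2, , ], unname(second[, 15000:1]))
  # involution: reversing the reversed copy recovers the window
  expect_equal(segs$data[2, , 15000:1], unname(second))
  # time reversal preserves per-channel moments (up to summation order)
  expect_equal(rowMeans(segs$data[2, , ]), unname(rowMeans(second)),
               tolerance = 1e-12)
  expect_equal(apply(segs$data[2, , ], 1, sd),
               unname(apply(second, 1, sd)), tolerance = 1e-12)

  one <- extract_segments(toy_recording(fs = 250, seconds = 90), 60)
  expect_equal(dim(one$data)[1], 1L)

  err <- expect_error(extract_segments(toy_recording(seconds = 4), 60),
                      class = "eegwave_too_short")
  expect_equal(err$duration, 4)
})

test_that("standardization gives zero mean unit sd, is idempotent, guards zeros", {
  segs <- tiny_segments()
  std <- standardize(segs)
  for (i in 1:2) {
    expect_equal(max(abs(rowMeans(std$data[i, , ]))), 0, tolerance = 1e-10)
    s <- sqrt(rowMeans(sweep(std$data[i, , ], 1,
                             rowMeans(std$data[i, , ]))^2))
    expect_equal(s, rep(1, dim(std$data)[2]), tolerance = 1e-6)
  }
  again <- standardize(std)
  expect_equal(again$data, std$data, tolerance = 1e-12)

  zs <- segs
  zs$data[1, 1, ] <- 0
  expect_warning(out <- standardize(zs), "zero-variance")
  expect_true(all(out$data[1, 1, ] == 0))
})

test_that("named preprocessing profiles produce the documented shapes", {
  rec <- toy_recording(fs = 500, seconds = 130, label = "normal")
  segs <- preprocess_pipeline(rec, "tuab")
  expect_equal(dim(segs$data), c(2L, 20L, 15000L))
  expect_equal(segs$fs, 250)
  expect_identical(segs$provenance, c("original", "reversed"))

  rec30 <- toy_recording(fs = 500, seconds = 40,
                         electrodes = standard_1020_30(), label = "abnormal")
  s30 <- preprocess_pipeline(rec30, "tuep")
  expect_equal(dim(s30$data), c(1L, 30L, 7500L))
  expect_identical(s30$provenance, "original")

  expect_error(preprocess_pipeline(toy_recording(fs = 250, seconds = 50),
                                   "tuab"),
               class = "eegwave_too_short")
})
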