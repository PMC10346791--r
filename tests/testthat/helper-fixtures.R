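# Shared fixtures: everything is generated in code at test time.

# deterministic multi-sine recording covering all 21 standard electrodes
toy_recording <- function(fs = 250, seconds = 4, electrodes = standard_1020_21(),
                          label = "unknown", seed = 1) {
  n <- fs * seconds
  t <- seq_len(n) / fs
  sig <- with_test_seed(seed, {
    do.call(rbind, lapply(seq_along(electrodes), function(i) {
      10 * sin(2 * pi * (5 + i) * t + i) + rnorm(n)
    }))
  })
  eeg_recording(sig, fs = fs, labels = electrodes, class_label = label)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# tiny network configuration for fast model/gradient tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_input_channels = 3, input_len = 40,
         block_dilations = list(c(1, 2), c(1, 2)), conv_filters = 4,
         kernel_size = 3, pool_factor = 2, path1_rnn_units = 5,
         window_len = 10, window_rnn_units = 4, path2_rnn_units = 5,
         path2_dense_units = 3, dropout = 0),
    list(...))
  do.call(model_config, args)
}

# tiny labelled segment set with a learnable class difference
tiny_segments <- function(n_per_class = 8, channels = 3, len = 40, fs = 10,
                          seed = 1) {
  with_test_seed(seed, {
    n <- 2 * n_per_class
    data <- array(rnorm(n * channels * len), c(n, channels, len))
    labels <- rep(c("normal", "abnormal"), each = n_per_class)
    t <- seq_len(len) / fs
    for (i in which(labels == "abnormal"))
      data[i, , ] <- data[i, , ] +
        matrix(3 * sin(2 * pi * 1.5 * t), channels, len, byrow = TRUE)
    segment_set(data, labels, fs = fs,
                provenance = rep("original", n),
                channel_names = paste0("ch", seq_len(channels)),
                recording_id = sprintf("rec-%02d", seq_len(n)))
  })
}

rms <- function(x) sqrt(mean(x^2))

# brute-force receptive-field probe: perturb each input sample and count
# how many of them reach the last output step of the dilation stack
probed_receptive_field <- function(dilations, kernel) {
  T_len <- receptive_field(dilations, kernel) + 20L
  with_test_seed(9, {
    ws <- lapply(seq_along(dilations), function(i)
      init_gated_weights(1L, 1L, kernel))
    x <- array(rnorm(T_len), c(1, T_len, 1))
    base <- wave_block(x, ws, dilations)$output[1, T_len, 1]
    affected <- vapply(seq_len(T_len), function(t) {
      xp <- x; xp[1, t, 1] <- xp[1, t, 1] + 0.5
      abs(wave_block(xp, ws, dilations)$output[1, T_len, 1] - base) > 1e-12
    }, logical(1))
    sum(affected)
  })
}
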