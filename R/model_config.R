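#' Model configuration
#'
#' All architecture hyperparameters of the dual-path network.  The defaults
#' are the reference configuration: a 20-channel, 60-s (15,000-sample at
#' 250 Hz) input; four wave blocks with dilation schedules
#' `[1..128], [1..64], [1..32], [1..16]`, 32 filters, kernel 3 and average
#' pooling by 4 after each block; a 64-unit LSTM tail on the convolutional
#' path; and a second path of 1-s windows encoded by a shared 32-unit LSTM,
#' channel-wise attention, a 64-unit LSTM with dropout and a 16-unit dense
#' layer.  The reference full model has 244,882 trainable parameters, within
#' the design budget of 244,992.
#'
#' @param n_input_channels input channels (20 for the TCP montage).
#' @param input_len input samples per segment; must be divisible by
#'   `window_len`.
#' @param block_dilations list of per-block dilation vectors, each strictly
#'   increasing and positive.
#' @param conv_filters convolution filters per block.
#' @param kernel_size convolution kernel taps.
#' @param pool_factor temporal average-pooling factor after each block.
#' @param path1_rnn_units LSTM units of the convolutional-path tail.
#' @param window_len samples per window in the second path.
#' @param window_rnn_units units of the shared window LSTM encoder.
#' @param path2_rnn_units units of the second-path LSTM.
#' @param path2_dense_units units of the second-path dense layer.
#' @param dropout dropout rate in `[0, 1)` applied after the second-path
#'   LSTM during training.
#' @param n_classes output classes.
#' @param param_budget maximum trainable parameters of the full model.
#' @return a `model_config` object.
#' @examples
#' cfg <- model_config()
#' count_parameters(cfg, "full")
#' @export
model_config <- function(n_input_channels = 20L,
                         input_len = 15000L,
                         block_dilations = list(2^(0:7), 2^(0:6), 2^(0:5),
                                                2^(0:4)),
                         conv_filters = 32L,
                         kernel_size = 3L,
                         pool_factor = 4L,
                         path1_rnn_units = 64L,
                         window_len = 250L,
                         window_rnn_units = 32L,
                         path2_rnn_units = 64L,
                         path2_dense_units = 16L,
                         dropout = 0.2,
                         n_classes = 2L,
                         param_budget = 244992L) {
  stopifnot(is_count(n_input_channels), n_input_channels >= 1,
            is_count(input_len), is_count(conv_filters),
            is_count(kernel_size), kernel_size >= 1,
            is_count(pool_factor), pool_factor >= 1,
            is_count(path1_rnn_units), is_count(window_len),
            is_count(window_rnn_units), is_count(path2_rnn_units),
            is_count(path2_dense_units),
            dropout >= 0, dropout < 1, is_count(n_classes), n_classes >= 2,
            is.list(block_dilations), length(block_dilations) >= 1)
  for (d in block_dilations) {
    if (any(d < 1) || any(d != round(d)) ||
        (length(d) > 1 && any(diff(d) <= 0)))
      stop_eegwave("each dilation schedule must be positive and strictly increasing",
                   "eegwave_parameter_error")
  }
  if (input_len %% window_len != 0)
    stop_eegwave("`input_len` must be divisible by `window_len`",
                 "eegwave_parameter_error")
  structure(list(
    n_input_channels = as.integer(n_input_channels),
    input_len = as.integer(input_len),
    block_dilations = lapply(block_dilations, as.integer),
    conv_filters = as.integer(conv_filters),
    kernel_size = as.integer(kernel_size),
    pool_factor = as.integer(pool_factor),
    path1_rnn_units = as.integer(path1_rnn_units),
    window_len = as.integer(window_len),
    window_rnn_units = as.integer(window_rnn_units),
    path2_rnn_units = as.integer(path2_rnn_units),
    path2_dense_units = as.integer(path2_dense_units),
    dropout = dropout, n_classes = as.integer(n_classes),
    param_budget = as.integer(param_budget)), class = "model_config")
}

#' Reduced reference configuration
#'
#' The scaled-down configuration used for desk-scale end-to-end experiments:
#' 10-s segments (2,500 samples at 250 Hz) and dilation schedules capped at
#' 32; everything else as in the reference.
#'
#' @param input_len input samples (default 2500).
#' @param dilation_cap maximum dilation retained in each block schedule.
#' @return a [model_config()].
#' @export
reduced_reference_config <- function(input_len = 2500L, dilation_cap = 32L) {
  cfg <- model_config()
  model_config(
    n_input_channels = cfg$n_input_channels,
    input_len = as.integer(input_len),
    block_dilations = lapply(cfg$block_dilations,
                             function(d) d[d <= dilation_cap]),
    conv_filters = cfg$conv_filters, kernel_size = cfg$kernel_size,
    pool_factor = cfg$pool_factor, path1_rnn_units = cfg$path1_rnn_units,
    window_len = cfg$window_len, window_rnn_units = cfg$window_rnn_units,
    path2_rnn_units = cfg$path2_rnn_units,
    path2_dense_units = cfg$path2_dense_units, dropout = cfg$dropout,
    n_classes = cfg$n_classes, param_budget = cfg$param_budget)
}

.variants <- c("baseline", "ablation1", "ablation2", "ablation3", "full")

check_variant <- function(variant) {
  if (!(is.character(variant) && length(variant) == 1L &&
        variant %in% .variants))
    stop_eegwave(sprintf("unknown variant '%s'; valid variants: %s",
                         paste(variant, collapse = ","),
                         paste(.variants, collapse = ", ")),
                 "eegwave_parameter_error")
  variant
}

variant_plan <- function(variant) {
  check_variant(variant)
  switch(variant,
    baseline  = list(path1 = TRUE,  tail = "gap",  path2 = FALSE),
    ablation1 = list(path1 = TRUE,  tail = "lstm", path2 = FALSE),
    ablation2 = list(path1 = TRUE,  tail = "gap",  path2 = TRUE),
    ablation3 = list(path1 = FALSE, tail = "none", path2 = TRUE),
    full      = list(path1 = TRUE,  tail = "lstm", path2 = TRUE))
}

n_dense <- function(n_in, n_out) n_in * n_out + n_out
n_conv <- function(c_in, k, f) c_in * k * f + f
n_lstm <- function(n_in, units) 4L * ((n_in + units) * units + units)

head_input_size <- function(cfg, variant) {
  plan <- variant_plan(variant)
  size <- 0L
  if (plan$path1)
    size <- size + if (plan$tail == "lstm") cfg$path1_rnn_units
                   else cfg$conv_filters
  if (plan$path2) size <- size + cfg$path2_dense_units
  size
}

#' Closed-form trainable-parameter count
#'
#' Sums the per-layer parameter formulas: `c_in*k*f + f` per convolution (two
#' gated convolutions plus one 1x1 residual projection per gated layer),
#' `4*((in + units)*units + units)` per LSTM (single-bias convention),
#' `in*out + out` per dense layer and `c*c + c` for the attention dense.
#' Average pooling, flipping, windowing, softmax and dropout carry no
#' parameters.  The result equals the element count of the weight arrays an
#' instantiated model actually allocates (see [build_model()]), which serves
#' as an independent cross-check.
#'
#' @param cfg a [model_config()].
#' @param variant one of `"baseline"`, `"ablation1"`, `"ablation2"`,
#'   `"ablation3"`, `"full"`.
#' @return integer parameter count.
#' @examples
#' count_parameters(model_config(), "full") # 244882
#' @export
count_parameters <- function(cfg, variant = "full") {
  stopifnot(inherits(cfg, "model_config"))
  plan <- variant_plan(variant)
  total <- 0L
  if (plan$path1) {
    c_in <- cfg$n_input_channels
    for (dil in cfg$block_dilations) {
      for (d in dil) {
        total <- total +
          2L * n_conv(c_in, cfg$kernel_size, cfg$conv_filters) +
          n_conv(c_in, 1L, cfg$conv_filters)
        c_in <- cfg$conv_filters
      }
    }
    if (plan$tail == "lstm")
      total <- total + n_lstm(cfg$conv_filters, cfg$path1_rnn_units)
  }
  if (plan$path2) {
    total <- total +
      n_lstm(cfg$n_input_channels, cfg$window_rnn_units) +
      n_dense(cfg$window_rnn_units, cfg$window_rnn_units) +   # attention
      n_lstm(cfg$window_rnn_units, cfg$path2_rnn_units) +
      n_dense(cfg$path2_rnn_units, cfg$path2_dense_units)
  }
  total + n_dense(head_input_size(cfg, variant), cfg$n_classes)
}

#' Per-layer parameter table
#'
#' @param cfg a [model_config()].
#' @param variant model variant.
#' @return a tibble with columns `layer` and `parameters`.
#' @export
parameter_table <- function(cfg, variant = "full") {
  stopifnot(inherits(cfg, "model_config"))
  plan <- variant_plan(variant)
  rows <- list()
  add <- function(layer, n) rows[[length(rows) + 1L]] <<-
    tibble::tibble(layer = layer, parameters = as.integer(n))
  if (plan$path1) {
    c_in <- cfg$n_input_channels
    for (j in seq_along(cfg$block_dilations)) {
      for (d in cfg$block_dilations[[j]]) {
        add(sprintf("block%d dilation %d (gated convs + 1x1 residual)", j, d),
            2L * n_conv(c_in, cfg$kernel_size, cfg$conv_filters) +
              n_conv(c_in, 1L, cfg$conv_filters))
        c_in <- cfg$conv_filters
      }
    }
    if (plan$tail == "lstm")
      add("path-1 LSTM", n_lstm(cfg$conv_filters, cfg$path1_rnn_units))
    else add("path-1 global average pooling", 0L)
  }
  if (plan$path2) {
    add("path-2 shared window LSTM",
        n_lstm(cfg$n_input_channels, cfg$window_rnn_units))
    add("path-2 channel attention",
        n_dense(cfg$window_rnn_units, cfg$window_rnn_units))
    add("path-2 LSTM", n_lstm(cfg$window_rnn_units, cfg$path2_rnn_units))
    add("path-2 dense", n_dense(cfg$path2_rnn_units, cfg$path2_dense_units))
  }
  add("softmax head", n_dense(head_input_size(cfg, variant), cfg$n_classes))
  out <- do.call(rbind, rows)
  out
}

#' Receptive field of a stacked causal dilated convolution
#'
#' For kernel size k and dilation schedule d_1..d_L the last output step sees
#' `1 + (k - 1) * sum(d)` input samples.
#'
#' @param dilations vector of dilation rates.
#' @param kernel kernel taps.
#' @return receptive field in samples.
#' @examples
#' receptive_field(2^(0:7), 3) # 511
#' @export
receptive_field <- function(dilations, kernel) {
  stopifnot(length(dilations) >= 1, all(dilations >= 1), kernel >= 1)
  as.integer(1 + (kernel - 1) * sum(dilations))
}
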