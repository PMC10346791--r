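# Dual-path network: construction, layer operations, forward and backward.
#
# Weight arrays live in a flat named list (model$params); compute-heavy
# primitives (causal dilated conv, LSTM, pooling) are compiled kernels, the
# rest is vectorized R.  Signal batches use the (channels, time, batch)
# layout expected by the kernels.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# --- initializers -----------------------------------------------------------

init_conv <- function(c_in, k, f) {
  # Glorot-uniform variance scaling; with the saturating gated activations
  # this keeps early activations out of the tails, which matters for
  # generalization at small sample sizes
  lim <- sqrt(6 / (c_in * k + f))
  w <- array(stats::runif(f * c_in * k, -lim, lim), dim = c(f, c_in, k))
  list(W = w, b = numeric(f))
}

init_dense <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in),
       b = numeric(n_out))
}

orthogonal_mat <- function(n) {
  qr_ <- qr(matrix(stats::rnorm(n * n), n))
  q <- qr.Q(qr_)
  q * sign(diag(qr.R(qr_)))  # fix sign ambiguity for a proper Haar draw
}

init_lstm <- function(n_in, units) {
  lim <- sqrt(6 / (n_in + units))
  Wx <- matrix(stats::runif(4 * units * n_in, -lim, lim), 4 * units, n_in)
  Wh <- do.call(rbind, replicate(4, orthogonal_mat(units), simplify = FALSE))
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1  # forget-gate bias
  list(Wx = Wx, Wh = Wh, b = b)
}

#' Initialize weights for one gated dilated layer
#'
#' Two causal dilated convolutions (filter and gate) plus the 1x1 residual
#' projection.
#'
#' @param c_in input channels.
#' @param filters output filters.
#' @param kernel kernel taps.
#' @return named list of weight arrays `Wf, bf, Wg, bg, Wp, bp`.
#' @export
init_gated_weights <- function(c_in, filters, kernel) {
  f <- init_conv(c_in, kernel, filters)
  g <- init_conv(c_in, kernel, filters)
  p <- init_conv(c_in, 1L, filters)
  list(Wf = f$W, bf = f$b, Wg = g$W, bg = g$b, Wp = p$W, bp = p$b)
}

# --- exported layer operations ---------------------------------------------

#' Gated dilated causal convolution layer
#'
#' Computes `gated = tanh(conv_f(x)) * sigmoid(conv_g(x))` with causal
#' (left-padded) dilated convolutions, plus a 1x1 convolution projecting the
#' input for the residual connection.  The chained output
#' `output = gated + proj` feeds the next layer; the pre-residual `gated`
#' output is what a wave block accumulates.
#'
#' @param x input array (channels, time, batch) or a channels-by-time matrix
#'   for a single example.
#' @param weights weight list as from [init_gated_weights()].
#' @param dilation dilation rate (>= 1).
#' @return list with arrays `output` and `gated`, both (filters, time,
#'   batch).
#' @export
gated_dilated_layer <- function(x, weights, dilation = 1L) {
  stopifnot(dilation >= 1)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  f <- conv_causal_fw(x, weights$Wf, weights$bf, as.integer(dilation))
  g <- conv_causal_fw(x, weights$Wg, weights$bg, as.integer(dilation))
  act <- gated_act_fw(f, g)
  proj <- conv_causal_fw(x, weights$Wp, weights$bp, 1L)
  list(output = act$gated + proj, gated = act$gated,
       .cache = list(tf = act$tf, sg = act$sg))
}

#' Wave block: chained gated layers with accumulated gated outputs
#'
#' Layers are chained through their residual outputs (layer i's `output`
#' feeds layer i+1); the block output is the element-wise sum of all layers'
#' pre-residual gated outputs.  No skip connections to the network head are
#' used.
#'
#' @param x input array (channels, time, batch) or matrix.
#' @param layer_weights list of per-layer weight lists (one per dilation).
#' @param dilations vector of dilation rates.
#' @return list with `output` (filters, time, batch) and `gated` (list of
#'   per-layer gated outputs).
#' @export
wave_block <- function(x, layer_weights, dilations) {
  stopifnot(length(layer_weights) == length(dilations))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  acc <- NULL
  gated_all <- vector("list", length(dilations))
  for (i in seq_along(dilations)) {
    out <- gated_dilated_layer(x, layer_weights[[i]], dilations[i])
    gated_all[[i]] <- out$gated
    acc <- if (is.null(acc)) out$gated else acc + out$gated
    x <- out$output
  }
  list(output = acc, gated = gated_all)
}

#' Channel-wise attention
#'
#' Attention weights `a = softmax(W %*% colMeans(h) + b)` over the channel
#' axis; the output scales every channel of `h` by its weight (broadcast
#' over steps).  Weights sum to 1.
#'
#' @param h steps-by-channels matrix.
#' @param W channels-by-channels weight matrix.
#' @param b length-channels bias.
#' @return the attended steps-by-channels matrix, with the weight vector in
#'   attribute `"weights"`.
#' @export
channel_attention <- function(h, W, b) {
  stopifnot(is.matrix(h), ncol(h) >= 1)
  m <- colMeans(h)
  a <- drop(softmax_cols(cbind(W %*% m + b)))
  out <- sweep(h, 2L, a, "*")
  attr(out, "weights") <- a
  out
}

# --- model construction -----------------------------------------------------

#' Build a dual-path network
#'
#' Instantiates the weight arrays for the requested variant:
#' * `"full"` - path 1: four wave blocks each followed by average pooling,
#'   then an LSTM taking the final hidden state; path 2: the input is
#'   time-reversed ("flipped"), split into `input_len / window_len` windows,
#'   each encoded by one shared LSTM, then channel-wise attention, an LSTM
#'   with dropout and a dense layer; both path outputs are concatenated into
#'   a softmax head.
#' * `"baseline"` - path 1 only, with the LSTM tail replaced by global
#'   temporal average pooling.
#' * `"ablation1"` - path 1 only (with LSTM tail).
#' * `"ablation2"` - both paths, path-1 tail replaced by global average
#'   pooling.
#' * `"ablation3"` - path 2 only.
#'
#' @param cfg a [model_config()].
#' @param variant model variant.
#' @param seed RNG seed for weight initialization.
#' @return a `wavenet_model` object.
#' @export
build_model <- function(cfg = model_config(), variant = "full", seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  plan <- variant_plan(variant)
  with_seed(seed, {
    p <- list()
    if (plan$path1) {
      c_in <- cfg$n_input_channels
      for (j in seq_along(cfg$block_dilations)) {
        for (i in seq_along(cfg$block_dilations[[j]])) {
          w <- init_gated_weights(c_in, cfg$conv_filters, cfg$kernel_size)
          for (nm in names(w)) p[[sprintf("b%d.l%d.%s", j, i, nm)]] <- w[[nm]]
          c_in <- cfg$conv_filters
        }
      }
      if (plan$tail == "lstm") {
        w <- init_lstm(cfg$conv_filters, cfg$path1_rnn_units)
        for (nm in names(w)) p[[paste0("p1.lstm.", nm)]] <- w[[nm]]
      }
    }
    if (plan$path2) {
      w <- init_lstm(cfg$n_input_channels, cfg$window_rnn_units)
      for (nm in names(w)) p[[paste0("p2.win.", nm)]] <- w[[nm]]
      w <- init_dense(cfg$window_rnn_units, cfg$window_rnn_units)
      p[["p2.att.W"]] <- w$W; p[["p2.att.b"]] <- w$b
      w <- init_lstm(cfg$window_rnn_units, cfg$path2_rnn_units)
      for (nm in names(w)) p[[paste0("p2.lstm.", nm)]] <- w[[nm]]
      w <- init_dense(cfg$path2_rnn_units, cfg$path2_dense_units)
      p[["p2.dense.W"]] <- w$W; p[["p2.dense.b"]] <- w$b
    }
    w <- init_dense(head_input_size(cfg, variant), cfg$n_classes)
    p[["head.W"]] <- w$W; p[["head.b"]] <- w$b
    structure(list(cfg = cfg, variant = variant, params = p),
              class = "wavenet_model")
  })
}

#' @export
print.wavenet_model <- function(x, ...) {
  cat(sprintf("<wavenet_model> variant '%s', %s trainable parameters\n",
              x$variant, format(model_parameter_count(x), big.mark = ",")))
  cat(sprintf("  input %d channels x %d samples; %d wave blocks\n",
              x$cfg$n_input_channels, x$cfg$input_len,
              length(x$cfg$block_dilations)))
  invisible(x)
}

#' Trainable parameters of an instantiated model
#'
#' Counts the elements of the weight arrays the model actually allocates -
#' the implementation's own counter, independent of the closed-form
#' [count_parameters()].
#'
#' @param model a `wavenet_model`.
#' @return integer count.
#' @export
model_parameter_count <- function(model) {
  stopifnot(inherits(model, "wavenet_model"))
  sum(vapply(model$params, length, integer(1)))
}

# --- forward ----------------------------------------------------------------

# X: (channels, time, batch).  Returns list(probs = n_classes x B, cache).
model_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  plan <- variant_plan(model$variant)
  p <- model$params
  B <- dim(X)[3L]
  cache <- list(B = B)
  feats <- list()

  if (plan$path1) {
    x <- X
    cache$blocks <- list()
    for (j in seq_along(cfg$block_dilations)) {
      dil <- cfg$block_dilations[[j]]
      bc <- list(T_in = dim(x)[2L], layers = vector("list", length(dil)))
      acc <- NULL
      for (i in seq_along(dil)) {
        w <- list(Wf = p[[sprintf("b%d.l%d.Wf", j, i)]],
                  bf = p[[sprintf("b%d.l%d.bf", j, i)]],
                  Wg = p[[sprintf("b%d.l%d.Wg", j, i)]],
                  bg = p[[sprintf("b%d.l%d.bg", j, i)]],
                  Wp = p[[sprintf("b%d.l%d.Wp", j, i)]],
                  bp = p[[sprintf("b%d.l%d.bp", j, i)]])
        f <- conv_causal_fw(x, w$Wf, w$bf, dil[i])
        g <- conv_causal_fw(x, w$Wg, w$bg, dil[i])
        act <- gated_act_fw(f, g)
        proj <- conv_causal_fw(x, w$Wp, w$bp, 1L)
        acc <- if (is.null(acc)) act$gated else acc + act$gated
        if (keep_cache)
          bc$layers[[i]] <- list(x = x, tf = act$tf, sg = act$sg)
        x <- act$gated + proj
      }
      x <- avgpool_fw(acc, cfg$pool_factor)
      if (keep_cache) { bc$acc_T <- dim(acc)[2L]; cache$blocks[[j]] <- bc }
    }
    cache$p1_in <- x  # (filters, T_final, B)
    if (plan$tail == "lstm") {
      st <- lstm_fw(x, p[["p1.lstm.Wx"]], p[["p1.lstm.Wh"]], p[["p1.lstm.b"]])
      feats$p1 <- st$h_last
      if (keep_cache) cache$p1_lstm <- st
    } else {
      feats$p1 <- apply(x, c(1L, 3L), mean)
      if (is.null(dim(feats$p1))) feats$p1 <- matrix(feats$p1, ncol = B)
    }
  }

  if (plan$path2) {
    Tn <- dim(X)[2L]
    nW <- Tn %/% cfg$window_len
    Xr <- X[, Tn:1, , drop = FALSE]                       # flip time
    Xw <- array(Xr, c(dim(X)[1L], cfg$window_len, nW * B)) # windows as batch
    win <- lstm_fw(Xw, p[["p2.win.Wx"]], p[["p2.win.Wh"]], p[["p2.win.b"]])
    H <- array(win$h_last, c(cfg$window_rnn_units, nW, B)) # (C=units, steps, B)
    m <- apply(H, c(1L, 3L), mean)
    if (is.null(dim(m))) m <- matrix(m, ncol = B)
    a <- softmax_cols(p[["p2.att.W"]] %*% m + p[["p2.att.b"]])  # (C, B)
    Ha <- H * aperm(array(a, c(cfg$window_rnn_units, B, nW)), c(1L, 3L, 2L))
    st2 <- lstm_fw(Ha, p[["p2.lstm.Wx"]], p[["p2.lstm.Wh"]], p[["p2.lstm.b"]])
    h2 <- st2$h_last
    if (training && cfg$dropout > 0) {
      mask <- matrix(stats::rbinom(length(h2), 1L, 1 - cfg$dropout),
                     nrow(h2)) / (1 - cfg$dropout)
      h2d <- h2 * mask
    } else {
      mask <- NULL
      h2d <- h2
    }
    pre <- p[["p2.dense.W"]] %*% h2d + p[["p2.dense.b"]]
    feats$p2 <- pmax(pre, 0)
    if (keep_cache)
      cache$p2 <- list(Xw = Xw, win = win, H = H, m = m, a = a, Ha = Ha,
                       st2 = st2, h2d = h2d, mask = mask, pre = pre,
                       nW = nW)
  }

  z <- do.call(rbind, feats)
  logits <- p[["head.W"]] %*% z + p[["head.b"]]
  probs <- softmax_cols(logits)
  cache$z <- z
  list(probs = probs, cache = if (keep_cache) cache else NULL)
}

# --- backward ---------------------------------------------------------------

# dlogits: (n_classes, B).  Returns flat named gradient list matching params.
model_backward <- function(model, X, cache, dlogits) {
  cfg <- model$cfg
  plan <- variant_plan(model$variant)
  p <- model$params
  gr <- list()
  B <- cache$B

  gr[["head.W"]] <- dlogits %*% t(cache$z)
  gr[["head.b"]] <- rowSums(dlogits)
  dz <- t(p[["head.W"]]) %*% dlogits
  at <- 0L
  if (plan$path1) {
    n1 <- if (plan$tail == "lstm") cfg$path1_rnn_units else cfg$conv_filters
    dp1 <- dz[at + seq_len(n1), , drop = FALSE]; at <- at + n1
  }
  if (plan$path2)
    dp2 <- dz[at + seq_len(cfg$path2_dense_units), , drop = FALSE]

  if (plan$path1) {
    if (plan$tail == "lstm") {
      st <- cache$p1_lstm
      bw <- lstm_bw(cache$p1_in, p[["p1.lstm.Wx"]], p[["p1.lstm.Wh"]],
                    st$G, st$C, st$H, dp1, TRUE)
      gr[["p1.lstm.Wx"]] <- bw$dWx
      gr[["p1.lstm.Wh"]] <- bw$dWh
      gr[["p1.lstm.b"]] <- as.numeric(bw$db)
      d <- bw$dX
    } else {
      Tf <- dim(cache$p1_in)[2L]
      d <- array(0, dim(cache$p1_in))
      for (bi in seq_len(B)) d[, , bi] <- dp1[, bi] / Tf
    }
    for (j in rev(seq_along(cfg$block_dilations))) {
      dil <- cfg$block_dilations[[j]]
      bc <- cache$blocks[[j]]
      d_acc <- avgpool_bw(d, cfg$pool_factor, bc$acc_T)
      dy <- NULL  # gradient w.r.t. the chained output of the current layer
      for (i in rev(seq_along(dil))) {
        lc <- bc$layers[[i]]
        d_gated <- if (is.null(dy)) d_acc else d_acc + dy
        dact <- gated_act_bw(d_gated, lc$tf, lc$sg)
        df_pre <- dact$df
        dg_pre <- dact$dg
        need_dx <- !(j == 1L && i == 1L)
        kf <- sprintf("b%d.l%d.", j, i)
        bwf <- conv_causal_bw(lc$x, p[[paste0(kf, "Wf")]], df_pre, dil[i],
                              need_dx)
        bwg <- conv_causal_bw(lc$x, p[[paste0(kf, "Wg")]], dg_pre, dil[i],
                              need_dx)
        dproj <- if (is.null(dy)) array(0, dim(d_acc)) else dy
        bwp <- conv_causal_bw(lc$x, p[[paste0(kf, "Wp")]], dproj, 1L,
                              need_dx)
        gr[[paste0(kf, "Wf")]] <- bwf$dW
        gr[[paste0(kf, "bf")]] <- as.numeric(bwf$db)
        gr[[paste0(kf, "Wg")]] <- bwg$dW
        gr[[paste0(kf, "bg")]] <- as.numeric(bwg$db)
        gr[[paste0(kf, "Wp")]] <- bwp$dW
        gr[[paste0(kf, "bp")]] <- as.numeric(bwp$db)
        if (need_dx) dy <- bwf$dX + bwg$dX + bwp$dX
      }
      d <- dy  # gradient w.r.t. block input = previous pooled output
    }
  }

  if (plan$path2) {
    c2 <- cache$p2
    drelu <- dp2 * (c2$pre > 0)
    gr[["p2.dense.W"]] <- drelu %*% t(c2$h2d)
    gr[["p2.dense.b"]] <- rowSums(drelu)
    dh2d <- t(p[["p2.dense.W"]]) %*% drelu
    dh2 <- if (is.null(c2$mask)) dh2d else dh2d * c2$mask
    bw2 <- lstm_bw(c2$Ha, p[["p2.lstm.Wx"]], p[["p2.lstm.Wh"]],
                   c2$st2$G, c2$st2$C, c2$st2$H, dh2, TRUE)
    gr[["p2.lstm.Wx"]] <- bw2$dWx
    gr[["p2.lstm.Wh"]] <- bw2$dWh
    gr[["p2.lstm.b"]] <- as.numeric(bw2$db)
    dHa <- bw2$dX                                  # (C, nW, B)
    C <- cfg$window_rnn_units
    a_exp <- aperm(array(c2$a, c(C, B, c2$nW)), c(1L, 3L, 2L))
    dH <- dHa * a_exp
    da <- apply(dHa * c2$H, c(1L, 3L), sum)        # (C, B)
    if (is.null(dim(da))) da <- matrix(da, ncol = B)
    ds <- c2$a * sweep(da, 2L, colSums(c2$a * da)) # softmax backward
    gr[["p2.att.W"]] <- ds %*% t(c2$m)
    gr[["p2.att.b"]] <- rowSums(ds)
    dm <- t(p[["p2.att.W"]]) %*% ds
    dH <- dH + aperm(array(dm / c2$nW, c(C, B, c2$nW)), c(1L, 3L, 2L))
    dh_win <- matrix(dH, C, c2$nW * B)
    bww <- lstm_bw(c2$Xw, p[["p2.win.Wx"]], p[["p2.win.Wh"]],
                   c2$win$G, c2$win$C, c2$win$H, dh_win, FALSE)
    gr[["p2.win.Wx"]] <- bww$dWx
    gr[["p2.win.Wh"]] <- bww$dWh
    gr[["p2.win.b"]] <- as.numeric(bww$db)
  }

  gr
}

# --- prediction -------------------------------------------------------------

segments_to_input <- function(segs) {
  stopifnot(inherits(segs, "segment_set"))
  aperm(segs$data, c(2L, 3L, 1L))
}

#' Predict class probabilities or classes
#'
#' @param object a `wavenet_model`.
#' @param newdata a [segment_set()] or a (segments, channels, samples) array.
#' @param type `"prob"` for a matrix of class probabilities (columns
#'   `normal`, `abnormal`), `"class"` for hard labels (probability ties break
#'   toward `normal`).
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return matrix of probabilities or character vector of labels.
#' @export
predict.wavenet_model <- function(object, newdata, type = c("prob", "class"),
                                  batch_size = 32L, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "segment_set")) segments_to_input(newdata)
       else newdata
  stopifnot(length(dim(X)) == 3L)
  n <- dim(X)[3L]
  probs <- matrix(0, n, object$cfg$n_classes,
                  dimnames = list(NULL, c("normal", "abnormal")))
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    fw <- model_forward(object, X[, , idx, drop = FALSE], training = FALSE)
    probs[idx, ] <- t(fw$probs)
  }
  if (type == "prob") return(probs)
  # ties (including exactly 0.5/0.5) break toward normal
  ifelse(probs[, "abnormal"] > probs[, "normal"], "abnormal", "normal")
}
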