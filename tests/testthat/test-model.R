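test_that("zero-weight gated layer outputs exactly zero", {
  w <- init_gated_weights(2, 3, 3)
  w <- lapply(w, function(a) a * 0)
  x <- array(rnorm(2 * 20), c(2, 20, 1))
  out <- gated_dilated_layer(x, w, dilation = 2)
  expect_true(all(out$gated == 0))  # tanh(0) * sigmoid(0) = 0 * 0.5
  expect_true(all(out$output == 0))
})

test_that("gated layers and wave blocks are causal under perturbation", {
  with_test_seed(3, {
    w <- init_gated_weights(2, 3, 3)
    x <- array(rnorm(2 * 50), c(2, 50, 1))
    y0 <- gated_dilated_layer(x, w, dilation = 4)$output
    t0 <- 20
    xp <- x; xp[1, t0, 1] <- xp[1, t0, 1] + 1
    y1 <- gated_dilated_layer(xp, w, dilation = 4)$output
    changed <- apply(abs(y1 - y0) > 1e-12, 2, any)
    expect_false(any(changed[seq_len(t0 - 1)]))
    expect_true(changed[t0])

    dil <- c(1, 2, 4)
    ws <- list(init_gated_weights(2, 3, 3), init_gated_weights(3, 3, 3),
               init_gated_weights(3, 3, 3))
    b0 <- wave_block(x, ws, dil)$output
    b1 <- wave_block(xp, ws, dil)$output
    changed <- apply(abs(b1 - b0) > 1e-12, 2, any)
    expect_false(any(changed[seq_len(t0 - 1)]))
  })
})

test_that("receptive field matches 1 + (k-1) * sum(dilations) by probing", {
  expect_equal(receptive_field(1, 2), 2L)
  expect_equal(receptive_field(c(1, 2, 4, 8), 2), 16L)
  expect_equal(receptive_field(2^(0:7), 3), 511L)
  expect_equal(probed_receptive_field(c(1, 2, 4, 8), 2), 16L)
  expect_equal(probed_receptive_field(c(1, 2, 4), 3), 15L)
  expect_equal(receptive_field(c(1, 2, 4), 3), 15L)
})

test_that("wave block accumulates the per-layer gated outputs", {
  with_test_seed(5, {
    dil <- c(1, 2, 4)
    ws <- list(init_gated_weights(2, 4, 3), init_gated_weights(4, 4, 3),
               init_gated_weights(4, 4, 3))
    x <- array(rnorm(2 * 30), c(2, 30, 1))
    out <- wave_block(x, ws, dil)
    # brute-force sum of the instrumented per-layer gated outputs
    expect_equal(out$output, Reduce(`+`, out$gated), tolerance = 1e-12)
    single <- wave_block(x, ws[1], 1)
    expect_equal(single$output, single$gated[[1]])
  })
})

test_that("channel attention weights normalize, default to uniform, and are permutation-equivariant", {
  with_test_seed(6, {
    h <- matrix(rnorm(10 * 4), 10, 4)
    W <- matrix(rnorm(16), 4, 4); b <- rnorm(4)
    out <- channel_attention(h, W, b)
    a <- attr(out, "weights")
    expect_equal(sum(a), 1, tolerance = 1e-6)
    expect_equal(out, sweep(h, 2, a, "*"), ignore_attr = TRUE)

    unif <- channel_attention(h, matrix(0, 4, 4), numeric(4))
    expect_equal(attr(unif, "weights"), rep(0.25, 4))

    perm <- c(3, 1, 4, 2)
    # rows of W and b follow the channel permutation; columns of W follow
    # the channel mean's permutation
    out_p <- channel_attention(h[, perm], W[perm, perm], b[perm])
    expect_equal(out_p, out[, perm], tolerance = 1e-12,
                 ignore_attr = TRUE)
  })
})

test_that("all variants produce valid softmax distributions", {
  cfg <- tiny_config()
  X <- with_test_seed(2, array(rnorm(3 * 40 * 4), c(3, 40, 4)))
  for (v in c("baseline", "ablation1", "ablation2", "ablation3", "full")) {
    m <- build_model(cfg, v, seed = 3)
    fw <- eegwave:::model_forward(m, X)
    expect_equal(dim(fw$probs), c(2L, 4L))
    expect_equal(colSums(fw$probs), rep(1, 4), tolerance = 1e-6)
    expect_true(all(fw$probs >= 0))
  }
  expect_error(build_model(cfg, "bogus"), "valid variants")
})

test_that("variant structure: baseline has no recurrent or path-2 weights", {
  m <- build_model(tiny_config(), "baseline", seed = 1)
  expect_false(any(grepl("lstm|p2\\.", names(m$params))))
  m3 <- build_model(tiny_config(), "ablation3", seed = 1)
  expect_false(any(grepl("^b[0-9]|p1\\.", names(m3$params))))
})

test_that("closed-form counts equal the instantiated counter for every variant", {
  for (cfg in list(tiny_config(), model_config())) {
    for (v in c("baseline", "ablation1", "ablation2", "ablation3", "full")) {
      expect_identical(count_parameters(cfg, v),
                       model_parameter_count(build_model(cfg, v, seed = 1)))
    }
    expect_identical(count_parameters(cfg, "full"),
                     sum(parameter_table(cfg, "full")$parameters))
  }
})

test_that("variant parameter counts nest as the architecture implies", {
  cfg <- model_config()
  p <- vapply(c("baseline", "ablation1", "ablation2", "ablation3", "full"),
              function(v) count_parameters(cfg, v), integer(1))
  expect_lt(p["baseline"], p["ablation1"])
  expect_lte(p["ablation1"], p["full"])
  expect_lt(p["ablation3"], p["full"])
  # ablation3 = path-2 weights plus its own head
  m3 <- build_model(cfg, "ablation3", seed = 1)
  mf <- build_model(cfg, "full", seed = 1)
  p2_full <- sum(vapply(mf$params[grepl("^p2\\.", names(mf$params))],
                        length, integer(1)))
  head3 <- length(m3$params$head.W) + length(m3$params$head.b)
  expect_identical(model_parameter_count(m3), p2_full + head3)
})

test_that("analytic gradients match finite differences on a tiny full model", {
  cfg <- tiny_config()
  m <- build_model(cfg, "full", seed = 7)
  with_test_seed(42, {
    B <- 3
    X <- array(rnorm(3 * 40 * B), c(3, 40, B))
    y <- eegwave:::one_hot(c("normal", "abnormal", "normal"))
    loss_of <- function(mm) {
      fw <- eegwave:::model_forward(mm, X)
      -mean(colSums(y * log(fw$probs + 1e-12)))
    }
    fw <- eegwave:::model_forward(m, X, keep_cache = TRUE)
    gr <- eegwave:::model_backward(m, X, fw$cache, (fw$probs - y) / B)
    eps <- 1e-6
    for (nm in c("b1.l1.Wf", "b2.l2.Wg", "b1.l2.Wp", "p1.lstm.Wh",
                 "p2.win.Wx", "p2.att.W", "p2.lstm.Wh", "p2.dense.W",
                 "head.W", "p2.win.b")) {
      for (j in sample(length(m$params[[nm]]), 2)) {
        mp <- m; mp$params[[nm]][j] <- mp$params[[nm]][j] + eps
        mm_ <- m; mm_$params[[nm]][j] <- mm_$params[[nm]][j] - eps
        num <- (loss_of(mp) - loss_of(mm_)) / (2 * eps)
        expect_equal(gr[[nm]][j], num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d]", nm, j))
      }
    }
  })
})

test_that("prediction ties break toward normal", {
  cfg <- tiny_config()
  m <- build_model(cfg, "baseline", seed = 1)
  # zero head weights force logits (0, 0) => probabilities exactly 0.5/0.5
  m$params$head.W[] <- 0
  m$params$head.b[] <- 0
  X <- array(rnorm(3 * 40 * 2), c(3, 40, 2))
  expect_identical(unname(predict(m, X, type = "class")),
                   c("normal", "normal"))
})
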