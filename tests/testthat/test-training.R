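test_that("stratified split hits per-class fractions and is reproducible", {
  segs <- tiny_segments(n_per_class = 50)  # 100 segments, one per recording
  sp <- stratified_split(segs, 0.3, seed = 4)
  expect_equal(sum(sp$val$labels == "normal"), 15L)
  expect_equal(sum(sp$val$labels == "abnormal"), 15L)
  expect_equal(n_segments(sp$train), 70L)
  expect_length(intersect(sp$train$recording_id, sp$val$recording_id), 0L)

  sp2 <- stratified_split(segs, 0.3, seed = 4)
  expect_identical(sp$val$recording_id, sp2$val$recording_id)

  ab_only <- subset_segments(segs, segs$labels == "abnormal")
  expect_error(stratified_split(ab_only, 0.3),
               class = "eegwave_stratification_error")
})

test_that("a segment and its time-reversed twin never straddle folds", {
  # simulated manifest: 30 recordings x (original + reversed) segments
  n_rec <- 30
  data <- array(rnorm(2 * n_rec * 2 * 20), c(2 * n_rec, 2, 20))
  segs <- segment_set(
    data, labels = rep(rep(c("normal", "abnormal"), each = n_rec / 2), 2),
    fs = 10, provenance = rep(c("original", "reversed"), each = n_rec),
    channel_names = c("a", "b"),
    recording_id = rep(sprintf("rec-%02d", seq_len(n_rec)), 2))
  for (seed in 1:5) {
    sp <- stratified_split(segs, 0.3, seed = seed)
    # exhaustive check over the fold assignment
    for (id in unique(segs$recording_id)) {
      in_train <- sum(sp$train$recording_id == id)
      in_val <- sum(sp$val$recording_id == id)
      expect_true(in_train == 0L || in_val == 0L)
      expect_equal(in_train + in_val, 2L)
    }
  }
})

test_that("balanced batches have per-batch class difference <= 1", {
  segs <- tiny_segments(n_per_class = 40)
  batches <- balanced_batches(segs, 17, seed = 1)
  for (b in batches) {
    counts <- table(factor(segs$labels[b],
                           levels = c("normal", "abnormal")))
    expect_lte(abs(counts[1] - counts[2]), 1L)
    expect_lte(length(b), 17L)
  }
  # full batches split 9/8
  full <- batches[lengths(batches) == 17L]
  expect_gt(length(full), 0L)
  for (b in full)
    expect_setequal(as.integer(table(segs$labels[b])), c(8L, 9L))
})

test_that("balanced batches cover the majority class and resample the minority", {
  # classes sized 100 / 10 at batch size 4 => every batch 2/2 with repeats
  data <- array(rnorm(110 * 2 * 10), c(110, 2, 10))
  segs <- segment_set(data,
                      labels = rep(c("normal", "abnormal"), c(100, 10)),
                      fs = 10, provenance = rep("original", 110),
                      channel_names = c("a", "b"),
                      recording_id = sprintf("r%03d", 1:110))
  batches <- balanced_batches(segs, 4, seed = 2)
  expect_equal(length(batches), 50L)  # ceiling(100 / 2)
  for (b in batches)
    expect_equal(as.integer(table(segs$labels[b])[c("normal", "abnormal")]),
                 c(2L, 2L))
  drawn <- unlist(batches)
  expect_setequal(intersect(drawn, 1:100), 1:100)  # majority covered
  minority_draws <- drawn[drawn > 100]
  expect_gt(length(minority_draws), length(unique(minority_draws)))

  # expected class prior seen by the optimizer is 1/2 despite 10:1 imbalance
  prior <- mean(segs$labels[drawn] == "abnormal")
  expect_equal(prior, 0.5, tolerance = 0.01)

  one_class <- subset_segments(segs, segs$labels == "normal")
  expect_error(balanced_batches(one_class, 4),
               class = "eegwave_stratification_error")
})

test_that("training rejects mismatched input shapes before any epoch", {
  segs <- tiny_segments()
  cfg <- tiny_config(n_input_channels = 5)  # segments have 3 channels
  m <- build_model(cfg, "baseline", seed = 1)
  expect_error(train_model(m, segs, segs, train_config(epochs = 1)),
               class = "eegwave_configuration_error")
})

test_that("training runs, improves, respects the lr floor and restores the best epoch", {
  segs <- standardize(tiny_segments(n_per_class = 10))
  sp <- stratified_split(segs, 0.3, seed = 2)
  m <- build_model(tiny_config(), "ablation1", seed = 2)
  cfg <- train_config(epochs = 12, batch_size = 4, patience_early_stop = 6,
                      patience_lr = 2, lr_init = 5e-3, lr_min = 2e-3,
                      seed = 3)
  res <- train_model(m, sp$train, sp$val, cfg)
  h <- res$history$metrics
  expect_lte(nrow(h), 12L)
  expect_true(all(diff(h$lr) <= 0))            # non-increasing trace
  expect_true(all(h$lr >= cfg$lr_min - 1e-15)) # never below the floor
  expect_equal(res$history$best_epoch, h$epoch[which.min(h$val_loss)])
  expect_lte(res$history$stopped_epoch, cfg$epochs)
  # returned model carries the best-epoch weights
  best <- eegwave:::eval_pass(res$model, sp$val)
  expect_equal(best$loss, min(h$val_loss), tolerance = 1e-10)
  # learnable toy problem: training loss decreases
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])

  g <- glance(res$history)
  expect_identical(g$best_epoch, res$history$best_epoch)
  expect_s3_class(tidy(res$history), "tbl_df")
})

test_that("training is deterministic given a seed", {
  segs <- standardize(tiny_segments(n_per_class = 6))
  sp <- stratified_split(segs, 0.34, seed = 1)
  cfg <- train_config(epochs = 3, batch_size = 4, seed = 11)
  r1 <- train_model(build_model(tiny_config(), "full", seed = 5),
                    sp$train, sp$val, cfg)
  r2 <- train_model(build_model(tiny_config(), "full", seed = 5),
                    sp$train, sp$val, cfg)
  expect_identical(r1$history$metrics$train_loss,
                   r2$history$metrics$train_loss)
  expect_identical(r1$history$metrics$val_loss, r2$history$metrics$val_loss)
})

test_that("early stopping fires after the configured patience without improvement", {
  # validation labels inverted relative to training: fitting the training
  # set makes validation loss worsen from the start, so training must stop
  # at (first epoch) + patience
  segs <- standardize(tiny_segments(n_per_class = 8))
  flipped <- segs
  flipped$labels <- ifelse(segs$labels == "normal", "abnormal", "normal")
  m <- build_model(tiny_config(), "ablation1", seed = 3)
  cfg <- train_config(epochs = 30, batch_size = 4, patience_early_stop = 3,
                      patience_lr = 2, seed = 2)
  res <- train_model(m, segs, flipped, cfg)
  h <- res$history
  expect_lt(h$stopped_epoch, 30L)
  expect_equal(h$stopped_epoch, h$best_epoch + cfg$patience_early_stop)
})
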