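#' Training configuration
#'
#' The balanced-training protocol: up to 50 epochs of Adam with batch size
#' 17 and class-balanced batches, cross-entropy loss, learning rate starting
#' at 0.001 and halved on a validation-loss plateau of 5 epochs down to a
#' floor of 1e-4, early stopping after 10 epochs without validation-loss
#' improvement (weights restored from the best epoch), and a 70/30
#' train/validation split.
#'
#' @param epochs maximum training epochs.
#' @param batch_size segments per batch.
#' @param lr_init initial Adam learning rate.
#' @param lr_min learning-rate floor.
#' @param lr_decay_factor multiplicative decay on plateau, in (0, 1).
#' @param patience_early_stop epochs without improvement before stopping.
#' @param patience_lr epochs without improvement before decaying the rate.
#' @param val_fraction validation fraction for [stratified_split()].
#' @param seed RNG seed for batching and dropout.
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 50L, batch_size = 17L, lr_init = 1e-3,
                         lr_min = 1e-4, lr_decay_factor = 0.5,
                         patience_early_stop = 10L, patience_lr = 5L,
                         val_fraction = 0.30, seed = 1L) {
  stopifnot(is_count(epochs), epochs >= 1, is_count(batch_size),
            batch_size >= 2, lr_init > 0, lr_min > 0, lr_min <= lr_init,
            lr_decay_factor > 0, lr_decay_factor < 1,
            is_count(patience_early_stop), patience_early_stop >= 1,
            is_count(patience_lr), patience_lr >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_min = lr_min, lr_decay_factor = lr_decay_factor,
                 patience_early_stop = as.integer(patience_early_stop),
                 patience_lr = as.integer(patience_lr),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/validation split grouped by source recording
#'
#' Splits per class so that validation counts are within one segment of the
#' exact fraction, keeping all segments of a source recording (an original
#' and its time-reversed twin) in the same fold - the leakage guard for
#' time-reverse augmentation.  Reproducible from `seed`.
#'
#' @param segs a [segment_set()] containing both classes.
#' @param val_fraction fraction of segments per class in the validation
#'   fold.
#' @param seed RNG seed.
#' @return list with [segment_set()] elements `train` and `val`.
#' @export
stratified_split <- function(segs, val_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(segs, "segment_set"),
            val_fraction > 0, val_fraction < 1)
  if (length(unique(segs$labels)) < 2L)
    stop_eegwave("stratified split needs both classes present",
                 "eegwave_stratification_error")
  rec <- segs$recording_id
  rec_label <- tapply(segs$labels, rec, function(x) x[1L])
  val_recs <- character(0)
  with_seed(seed, {
    for (cl in unique(rec_label)) {
      ids <- names(rec_label)[rec_label == cl]
      n_seg_cl <- sum(segs$labels == cl)
      target <- round(val_fraction * n_seg_cl)
      ids <- sample(ids)
      got <- 0L; take <- character(0)
      for (id in ids) {
        if (got >= target) break
        take <- c(take, id)
        got <- got + sum(rec == id)
      }
      val_recs <- c(val_recs, take)
    }
  })
  in_val <- rec %in% val_recs
  list(train = subset_segments(segs, !in_val),
       val = subset_segments(segs, in_val))
}

#' Class-balanced batches
#'
#' Each batch holds the two classes in counts differing by at most one (9/8
#' for batch size 17).  The larger class is partitioned across the epoch
#' without replacement (so every one of its segments is seen), the smaller
#' class is resampled with replacement; order is reshuffled per epoch from
#' `seed`.
#'
#' @param segs a [segment_set()] with both classes non-empty.
#' @param batch_size segments per batch.
#' @param seed RNG seed.
#' @return list of integer index vectors into `segs`, one per batch.
#' @export
balanced_batches <- function(segs, batch_size = 17L, seed = 1L) {
  stopifnot(inherits(segs, "segment_set"), batch_size >= 2)
  classes <- c("normal", "abnormal")
  idx <- lapply(classes, function(cl) which(segs$labels == cl))
  names(idx) <- classes
  if (any(lengths(idx) == 0L))
    stop_eegwave("balanced batches need both classes non-empty",
                 "eegwave_stratification_error")
  maj <- classes[which.max(lengths(idx))]
  mino <- setdiff(classes, maj)
  n_maj_per <- as.integer(ceiling(batch_size / 2))
  with_seed(seed, {
    maj_idx <- sample(idx[[maj]])
    n_batches <- ceiling(length(maj_idx) / n_maj_per)
    lapply(seq_len(n_batches), function(b) {
      lo <- (b - 1L) * n_maj_per + 1L
      hi <- min(b * n_maj_per, length(maj_idx))
      take_maj <- maj_idx[lo:hi]
      n_min <- max(1L, length(take_maj) - (batch_size %% 2L))
      take_min <- sample(idx[[mino]], n_min, replace = TRUE)
      sample(c(take_maj, take_min))
    })
  })
}

one_hot <- function(labels) {
  y <- matrix(0, 2L, length(labels))
  y[1L, labels == "normal"] <- 1
  y[2L, labels == "abnormal"] <- 1
  y
}

# mean cross-entropy and accuracy of a probability matrix (2 x B)
loss_acc <- function(probs, labels) {
  y <- one_hot(labels)
  eps <- 1e-12
  loss <- -mean(colSums(y * log(probs + eps)))
  pred <- ifelse(probs[2L, ] > probs[1L, ], "abnormal", "normal")
  list(loss = loss, acc = mean(pred == labels))
}

eval_pass <- function(model, segs, batch_size = 32L) {
  X <- segments_to_input(segs)
  n <- dim(X)[3L]
  probs <- matrix(0, 2L, n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    probs[, idx] <- model_forward(model, X[, , idx, drop = FALSE])$probs
  }
  loss_acc(probs, segs$labels)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# clip the global gradient norm; stabilizes early recurrent training
clip_global_norm <- function(grads, max_norm = 5) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  grads
}

#' Train a model
#'
#' Minimizes cross-entropy with Adam over class-balanced batches.  The
#' learning rate is multiplied by `lr_decay_factor` when the validation loss
#' has not improved for `patience_lr` epochs (never below `lr_min`);
#' training stops after `patience_early_stop` epochs without improvement and
#' the weights from the best epoch (minimum validation loss) are returned.
#'
#' @param model a [build_model()] model whose input shape matches `train`.
#' @param train,val [segment_set()] folds, e.g. from [stratified_split()].
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with elements `model` (weights from the best epoch) and
#'   `history` (a `train_history`: per-epoch losses, accuracies,
#'   learning-rate trace, `best_epoch`, `stopped_epoch`).
#' @export
train_model <- function(model, train, val, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "wavenet_model"), inherits(train, "segment_set"),
            inherits(val, "segment_set"), inherits(cfg, "train_config"))
  d <- dim(train$data)
  if (d[2L] != model$cfg$n_input_channels || d[3L] != model$cfg$input_len)
    stop_eegwave(sprintf(
      "segment shape (%d channels x %d samples) does not match model input (%d x %d)",
      d[2L], d[3L], model$cfg$n_input_channels, model$cfg$input_len),
      "eegwave_configuration_error")
  Xall <- segments_to_input(train)
  state <- adam_init(model$params)
  lr <- cfg$lr_init
  best_loss <- Inf; best_epoch <- 0L; best_params <- model$params
  since_improve <- 0L; since_lr <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0), lr = numeric(0))
  stopped <- cfg$epochs
  for (epoch in seq_len(cfg$epochs)) {
    batches <- balanced_batches(train, cfg$batch_size,
                                seed = cfg$seed + 1000L * epoch)
    tl <- 0; ta <- 0; nb <- 0
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      X <- Xall[, , idx, drop = FALSE]
      with_seed(cfg$seed + 100000L * epoch + b, {
        fw <- model_forward(model, X, training = TRUE, keep_cache = TRUE)
      })
      la <- loss_acc(fw$probs, train$labels[idx])
      y <- one_hot(train$labels[idx])
      dlogits <- (fw$probs - y) / length(idx)
      gr <- model_backward(model, X, fw$cache, dlogits)
      gr <- clip_global_norm(gr)
      upd <- adam_step(model$params, gr, state, lr)
      model$params <- upd$params
      state <- upd$state
      tl <- tl + la$loss; ta <- ta + la$acc; nb <- nb + 1
    }
    vm <- eval_pass(model, val)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / nb,
                                   train_acc = ta / nb, val_loss = vm$loss,
                                   val_acc = vm$acc, lr = lr))
    if (verbose)
      message(sprintf(
        "epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f | lr %g",
        epoch, tl / nb, ta / nb, vm$loss, vm$acc, lr))
    if (vm$loss < best_loss - 1e-10) {
      best_loss <- vm$loss; best_epoch <- epoch
      best_params <- model$params
      since_improve <- 0L; since_lr <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_lr <- since_lr + 1L
      if (since_lr >= cfg$patience_lr && lr > cfg$lr_min) {
        lr <- max(lr * cfg$lr_decay_factor, cfg$lr_min)
        since_lr <- 0L
      }
      if (since_improve >= cfg$patience_early_stop) {
        stopped <- epoch
        break
      }
    }
  }
  model$params <- best_params
  history <- structure(list(metrics = hist, best_epoch = best_epoch,
                            stopped_epoch = stopped),
                       class = "train_history")
  list(model = model, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history> %d epochs (stopped at %d, best %d)\n",
              nrow(x$metrics), x$stopped_epoch, x$best_epoch))
  print(utils::tail(x$metrics, 3L), row.names = FALSE)
  invisible(x)
}

#' Tidy a training history
#' @param x a `train_history`.
#' @param ... unused.
#' @return a tibble of per-epoch metrics.
#' @export
tidy.train_history <- function(x, ...) tibble::as_tibble(x$metrics)

#' One-line training summary
#' @param x a `train_history`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.train_history <- function(x, ...) {
  b <- x$metrics[x$metrics$epoch == x$best_epoch, ]
  tibble::tibble(epochs_run = nrow(x$metrics), best_epoch = x$best_epoch,
                 stopped_epoch = x$stopped_epoch,
                 best_val_loss = b$val_loss, best_val_acc = b$val_acc,
                 final_lr = x$metrics$lr[nrow(x$metrics)])
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
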