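# Training: cross-entropy objective under AdamW, plateau learning-rate decay
# (x lr_decay_factor after plateau_patience epochs without improvement of
# the monitored metric) and early stopping (after early_stop_patience epochs
# without improvement). The schedule logic is a pure state machine so it can
# be exercised against hand-simulated metric sequences.

#' Training configuration
#'
#' Defaults follow the published schedule: AdamW with learning rate 1e-4 and
#' weight decay 1e-4, up to 100 epochs, dropout handled by the model, early
#' stopping with patience 20, and learning-rate decay to 80% of the current
#' value after 10 consecutive epochs without improvement of the monitored
#' validation metric. Improvement means a strict increase; ties keep the
#' earlier best epoch. A decay does not reset the early-stopping counter.
#'
#' @param learning_rate initial AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param max_epochs training epoch cap.
#' @param batch_size minibatch size (the source material leaves it unstated;
#'   32 is the default here).
#' @param early_stop_patience epochs without improvement before stopping.
#' @param plateau_patience epochs without improvement before an LR decay.
#' @param lr_decay_factor multiplicative decay factor in (0, 1).
#' @param monitor monitored metric; `"val_top1"` (validation Top-1).
#' @param val_fraction fraction of the training set carved off (stratified)
#'   as the validation set when none is supplied.
#' @param seed seed for shuffling, dropout and augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         max_epochs = 100L, batch_size = 32L,
                         early_stop_patience = 20L, plateau_patience = 10L,
                         lr_decay_factor = 0.8, monitor = "val_top1",
                         val_fraction = 0.1, seed = 123L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, max_epochs >= 1,
            batch_size >= 1, early_stop_patience >= 1, plateau_patience >= 1,
            plateau_patience <= early_stop_patience,
            lr_decay_factor > 0, lr_decay_factor < 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 plateau_patience = as.integer(plateau_patience),
                 lr_decay_factor = lr_decay_factor, monitor = monitor,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

# Schedule state machine ------------------------------------------------------

schedule_init <- function(cfg) {
  list(lr = cfg$learning_rate, best = -Inf, best_epoch = 0L,
       since_improve = 0L, plateau_count = 0L, stop = FALSE, decayed = FALSE)
}

schedule_update <- function(state, metric, epoch, cfg) {
  state$decayed <- FALSE
  if (metric > state$best) {
    state$best <- metric
    state$best_epoch <- epoch
    state$since_improve <- 0L
    state$plateau_count <- 0L
  } else {
    state$since_improve <- state$since_improve + 1L
    state$plateau_count <- state$plateau_count + 1L
    if (state$plateau_count >= cfg$plateau_patience) {
      state$lr <- state$lr * cfg$lr_decay_factor
      state$plateau_count <- 0L
      state$decayed <- TRUE
    }
    if (state$since_improve >= cfg$early_stop_patience) state$stop <- TRUE
  }
  state
}

#' Simulate the learning-rate / early-stopping schedule
#'
#' Runs the schedule state machine over a hand-supplied sequence of monitored
#' metric values (no model involved): learning rate multiplied by the decay
#' factor whenever the metric has failed to improve for `plateau_patience`
#' consecutive epochs, training stopped after `early_stop_patience` epochs
#' without improvement or at `max_epochs`.
#'
#' @param metrics numeric vector of per-epoch monitored values.
#' @param cfg a [train_config()].
#' @return data frame (`epoch`, `metric`, `lr`, `decayed`) with attributes
#'   `best_epoch`, `stop_epoch` and `stop_reason`.
#' @export
simulate_schedule <- function(metrics, cfg = train_config()) {
  st <- schedule_init(cfg)
  n <- min(length(metrics), cfg$max_epochs)
  out <- data.frame(epoch = seq_len(n), metric = metrics[seq_len(n)],
                    lr = NA_real_, decayed = FALSE)
  stop_epoch <- n
  stop_reason <- "max_epochs"
  for (e in seq_len(n)) {
    st <- schedule_update(st, metrics[e], e, cfg)
    out$lr[e] <- st$lr
    out$decayed[e] <- st$decayed
    if (st$stop) {
      stop_epoch <- e
      stop_reason <- "early_stop"
      break
    }
  }
  out <- out[seq_len(stop_epoch), , drop = FALSE]
  attr(out, "best_epoch") <- st$best_epoch
  attr(out, "stop_epoch") <- stop_epoch
  attr(out, "stop_reason") <- stop_reason
  out
}

# Datasets --------------------------------------------------------------------

#' Load an image dataset into memory
#'
#' Reads every record's image, letterboxes it to `image_size` and stacks the
#' batch tensor; labels are the remapped 0-based class indices.
#'
#' @param records metadata data frame (expert-filtered) with `path` set.
#' @param image_size model input side length.
#' @return a `wheat_dataset` list with `x` (`[3, S, S, M]`), `y` (0-based
#'   labels) and `ids`.
#' @export
make_dataset <- function(records, image_size = 256L) {
  stopifnot(nrow(records) >= 1L, !anyNA(records$path))
  m <- nrow(records)
  x <- array(0, dim = c(3L, image_size, image_size, m))
  for (j in seq_len(m)) x[, , , j] <- load_image(records$path[j], image_size)
  structure(list(x = x, y = remap_stage(records$stage),
                 ids = records$image_id),
            class = "wheat_dataset")
}

dataset_size <- function(ds) length(ds$y)

dataset_subset <- function(ds, idx) {
  structure(list(x = ds$x[, , , idx, drop = FALSE], y = ds$y[idx],
                 ids = ds$ids[idx]),
            class = "wheat_dataset")
}

# Stratified carve-out of a validation split from an in-memory dataset.
split_validation <- function(ds, fraction, seed) {
  val_idx <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(ds$y))) {
      idx <- which(ds$y == cl)
      n_val <- max(1L, floor(fraction * length(idx) + 0.5))
      val_idx <- c(val_idx, sample(idx, min(n_val, length(idx))))
    }
  })
  list(train = dataset_subset(ds, setdiff(seq_len(dataset_size(ds)), val_idx)),
       val = dataset_subset(ds, sort(val_idx)))
}

# Objective -------------------------------------------------------------------

# Numerically stable cross entropy on logits [K, N]; returns the mean loss
# and the logits gradient (softmax - onehot) / N.
cross_entropy <- function(logits, y) {
  k <- nrow(logits)
  n <- ncol(logits)
  shifted <- logits - rep(apply(logits, 2, max), each = k)
  lse <- log(colSums(exp(shifted)))
  idx <- cbind(y + 1L, seq_len(n))
  loss <- mean(lse - shifted[idx])
  probs <- exp(shifted - rep(lse, each = k))
  grad <- probs
  grad[idx] <- grad[idx] - 1
  list(loss = loss, grad = grad / n)
}

# Training --------------------------------------------------------------------

#' Train a growth-stage network
#'
#' Minimises cross entropy with AdamW under the configured schedule. The
#' monitored metric is validation Top-1 accuracy; the returned model carries
#' the weights of the best epoch. Fully reproducible given `cfg$seed`.
#'
#' @param model a [build_model()] network.
#' @param train_set a `wheat_dataset` (see [make_dataset()]).
#' @param val_set optional validation `wheat_dataset`; when `NULL`, a
#'   stratified `cfg$val_fraction` carve-out of `train_set` is used.
#' @param cfg a [train_config()].
#' @param augment optional [augment_config()] applied to each training image
#'   each epoch (`NULL` = no augmentation).
#' @param log_file optional path for a JSON-lines training log.
#' @param verbose print one line per epoch.
#' @return a `wheat_fit` list: `model` (best weights), `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`, `val_top1`, `lr`, `seconds`, and
#'   mean fusion weights for the amsaf variant), `best_epoch`,
#'   `stop_reason`.
#' @export
train_model <- function(model, train_set, val_set = NULL,
                        cfg = train_config(), augment = NULL,
                        log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.null(val_set)) {
    sv <- split_validation(train_set, cfg$val_fraction, cfg$seed)
    train_set <- sv$train
    val_set <- sv$val
  }
  if (dataset_size(train_set) == 0L || dataset_size(val_set) == 0L) {
    stop("training and validation sets must be non-empty")
  }
  set.seed(cfg$seed)
  opt <- adamw_init(nn_parameters(model), lr = cfg$learning_rate,
                    weight_decay = cfg$weight_decay)
  st <- schedule_init(cfg)
  n <- dataset_size(train_set)
  history <- list()
  best_state <- nn_state_dict(model)
  stop_reason <- "max_epochs"
  log_con <- if (!is.null(log_file)) file(log_file, open = "wt") else NULL
  on.exit(if (!is.null(log_con)) close(log_con), add = TRUE)

  for (epoch in seq_len(cfg$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    nn_set_training(model, TRUE)
    ord <- sample.int(n)
    losses <- numeric(0)
    wfa_sum <- NULL
    n_batches <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(n, start + cfg$batch_size - 1L)]
      xb <- train_set$x[, , , idx, drop = FALSE]
      if (!is.null(augment)) {
        for (j in seq_along(idx)) {
          xb[, , , j] <- augment_image(xb[, , , j], augment,
                                       sample_seed = epoch * 100003L + idx[j])
        }
      }
      out <- nn_forward(model, xb)
      ce <- cross_entropy(out$logits, train_set$y[idx])
      if (!is.finite(ce$loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             " (batch starting at ", start, ")")
      }
      losses <- c(losses, ce$loss)
      if (!is.null(out$weights)) {
        wmean <- rowMeans(out$weights)
        wfa_sum <- if (is.null(wfa_sum)) wmean else wfa_sum + wmean
      }
      n_batches <- n_batches + 1L
      nn_backward(model, ce$grad)
      opt$lr <- st$lr
      opt <- adamw_step(opt)
      nn_zero_grad(model)
    }
    val <- evaluate_scores(model, val_set, cfg$batch_size)
    val_ce <- cross_entropy(t(log(pmax(val$probs, 1e-12))), val_set$y)
    val_top1 <- top1_accuracy(val_set$y, val$pred)
    st <- schedule_update(st, val_top1, epoch, cfg)
    improved <- st$best_epoch == epoch
    if (improved) best_state <- nn_state_dict(model)
    rec <- data.frame(epoch = epoch, train_loss = mean(losses),
                      val_loss = val_ce$loss, val_top1 = val_top1, lr = st$lr,
                      seconds = proc.time()[["elapsed"]] - t0)
    if (!is.null(wfa_sum)) {
      wavg <- wfa_sum / n_batches
      rec$wfa_w1 <- wavg[1]; rec$wfa_w2 <- wavg[2]
      rec$wfa_w3 <- wavg[3]; rec$wfa_w4 <- wavg[4]
    }
    history[[epoch]] <- rec
    if (!is.null(log_con)) {
      writeLines(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE,
                                  digits = NA), log_con)
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_top1 %.4f  lr %.2e%s",
                      epoch, mean(losses), val_top1, st$lr,
                      if (improved) "  *" else ""))
    }
    if (st$stop) {
      stop_reason <- "early_stop"
      break
    }
  }
  nn_load_state_dict(model, best_state)
  nn_set_training(model, FALSE)
  structure(list(model = model, history = do.call(rbind, history),
                 best_epoch = st$best_epoch, stop_reason = stop_reason,
                 config = cfg),
            class = "wheat_fit")
}

# Inference over a dataset in batches; returns probs [M, K] and pred.
evaluate_scores <- function(model, ds, batch_size = 64L) {
  nn_set_training(model, FALSE)
  m <- dataset_size(ds)
  k <- model$config$num_classes
  probs <- matrix(0, m, k)
  for (start in seq(1L, m, by = batch_size)) {
    idx <- start:min(m, start + batch_size - 1L)
    out <- nn_forward(model, ds$x[, , , idx, drop = FALSE])
    probs[idx, ] <- t(softmax_cols(out$logits))
  }
  list(probs = probs, pred = max.col(probs, ties.method = "first") - 1L)
}

#' Evaluate a model on a test dataset
#'
#' Inference-mode forward over the whole set, returning the full metric
#' report (confusion matrix, Top-1, per-class battery, OvR AUC summaries).
#' Deterministic for a fixed model and dataset.
#'
#' @param model a trained network (or a `wheat_fit`, whose model is used).
#' @param test_set a `wheat_dataset`.
#' @param batch_size inference batch size.
#' @return a [metric_report()] object.
#' @export
evaluate_model <- function(model, test_set, batch_size = 64L) {
  if (inherits(model, "wheat_fit")) model <- model$model
  if (model$config$num_classes != length(stage_map()$indices) &&
      max(test_set$y) >= model$config$num_classes) {
    stop("dataset labels exceed the model's ", model$config$num_classes,
         " classes")
  }
  sc <- evaluate_scores(model, test_set, batch_size)
  metric_report(test_set$y, sc$probs)
}

# Checkpoints -----------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' `save_checkpoint` writes the serialized weights and configuration plus a
#' human-readable JSON sidecar (`<path>.json`) carrying the configuration and
#' the parameter audit. `load_checkpoint` rebuilds the model and restores the
#' weights; a save/load round trip reproduces evaluation outputs exactly.
#'
#' @param model a built (possibly trained) network.
#' @param path checkpoint file path (`.rds`).
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "wheat_fit")) model <- model$model
  saveRDS(list(config = model$config, state = nn_state_dict(model)), path)
  audit <- parameter_audit(model)
  jsonlite::write_json(list(config = unclass(model$config),
                            audit = as.data.frame(audit)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$config
  class(cfg) <- "wheat_model_config"
  model <- build_model(cfg)
  nn_load_state_dict(model, ck$state)
  model
}
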