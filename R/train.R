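# The optimization recipe: SGD with step learning-rate decay, L2 weight
# decay, mini-batches with training-time augmentation, per-epoch validation,
# and best-validation-epoch selection.

#' Bundle volumes and labels into a dataset
#'
#' @param volumes list of equally-shaped 3D arrays.
#' @param age numeric ages in years (age task), or `NULL`.
#' @param sex integer 0/1 labels (sex task), or `NULL`.
#' @param id optional subject identifiers.
#' @return an object of class `volume_dataset`.
#' @export
volume_dataset <- function(volumes, age = NULL, sex = NULL, id = NULL) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  d <- dim(volumes[[1]])
  if (length(d) != 3L || !all(vapply(volumes, function(v)
    identical(dim(v), d), logical(1))))
    stop("all volumes must be 3D arrays of identical shape")
  n <- length(volumes)
  if (!is.null(age) && length(age) != n) stop("age length mismatch")
  if (!is.null(sex) && length(sex) != n) stop("sex length mismatch")
  if (is.null(id)) id <- sprintf("sub-%04d", seq_len(n))
  structure(list(volumes = volumes, age = age, sex = sex, id = id),
            class = "volume_dataset")
}

#' @export
length.volume_dataset <- function(x) length(x$volumes)

#' @export
`[.volume_dataset` <- function(x, i) {
  volume_dataset(x$volumes[i],
                 age = if (!is.null(x$age)) x$age[i],
                 sex = if (!is.null(x$sex)) x$sex[i],
                 id = x$id[i])
}

#' Training configuration
#'
#' Defaults follow the reference recipe: SGD, initial learning rate 0.01
#' multiplied by 0.3 every 30 epochs, L2 weight decay 0.001, batch size 8,
#' Gaussian soft labels of width `label_sigma` (1 year on one-year bins),
#' voxel-shift and sagittal-mirror augmentation during training only.
#' Momentum 0.9 is an assumption (the standard companion of this schedule);
#' set `momentum = 0` to disable. Adam is retained as a comparison option
#' with conventional defaults.
#'
#' @param total_epochs number of training epochs.
#' @param optimizer `"sgd"` or `"adam"`.
#' @param lr_init initial learning rate.
#' @param lr_factor multiplicative decay factor (in (0, 1)).
#' @param lr_step epochs between decays.
#' @param weight_decay L2 coefficient applied to all parameters.
#' @param momentum SGD momentum.
#' @param batch_size mini-batch size.
#' @param seed integer seed covering shuffling, augmentation and dropout.
#' @param task `"age_bins"` or `"sex_binary"`.
#' @param bins an [age_bins()] object (required for the age task).
#' @param label_sigma soft-label Gaussian width in years.
#' @param augment an [augment_config()].
#' @param checkpoint_dir optional directory for per-epoch checkpoints.
#' @param checkpoint_every save every k-th epoch (0 = none unless
#'   `checkpoint_dir` is set, then every epoch).
#' @param run_name label used in checkpoint filenames and logs.
#' @param verbose print a line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(total_epochs, optimizer = c("sgd", "adam"),
                         lr_init = 0.01, lr_factor = 0.3, lr_step = 30L,
                         weight_decay = 0.001, momentum = 0.9,
                         batch_size = 8L, seed = 1L,
                         task = c("age_bins", "sex_binary"), bins = NULL,
                         label_sigma = NULL, augment = augment_config(),
                         checkpoint_dir = NULL, checkpoint_every = 1L,
                         run_name = "run", verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  task <- match.arg(task)
  if (lr_init <= 0) stop("lr_init must be positive")
  if (lr_factor <= 0 || lr_factor >= 1) stop("lr_factor must be in (0, 1)")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (task == "age_bins") {
    if (is.null(bins)) stop("the age task requires `bins`")
    if (is.null(label_sigma)) label_sigma <- bins$bin_width
  }
  structure(list(total_epochs = as.integer(total_epochs),
                 optimizer = optimizer, lr_init = lr_init,
                 lr_factor = lr_factor, lr_step = as.integer(lr_step),
                 weight_decay = weight_decay, momentum = momentum,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 task = task, bins = bins, label_sigma = label_sigma,
                 augment = augment, checkpoint_dir = checkpoint_dir,
                 checkpoint_every = as.integer(checkpoint_every),
                 run_name = run_name, verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr_init * lr_factor^floor((epoch - 1) / lr_step)`. Epochs are
#' numbered from 1, so epoch 1 uses `lr_init` and the first decay applies at
#' epoch `lr_step + 1` (with the defaults: 0.01 for epochs 1-30, 0.003 for
#' 31-60, and so on).
#'
#' @param cfg a [train_config()].
#' @param epoch epoch number (1-based).
#' @return the learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  stopifnot(epoch >= 1)
  cfg$lr_init * cfg$lr_factor^((as.integer(epoch) - 1L) %/% cfg$lr_step)
}

dataset_labels <- function(set, task) {
  lab <- if (task == "age_bins") set$age else set$sex
  if (is.null(lab)) stop("dataset lacks the labels required by task ", task)
  lab
}

# Targets as a C x N matrix.
make_targets <- function(labels, cfg) {
  if (cfg$task == "age_bins") {
    t <- soft_label(labels, cfg$bins, cfg$label_sigma)
    if (is.null(dim(t))) t <- matrix(t, ncol = 1L)
    t
  } else {
    t <- matrix(0, 2L, length(labels))
    t[cbind(labels + 1L, seq_along(labels))] <- 1
    t
  }
}

# Forward a dataset in evaluation mode; returns the n x C probability matrix.
predict_probs <- function(net, volumes, batch_size = 8L) {
  n <- length(volumes)
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    p <- network_forward(net, volumes[idx], training = FALSE)
    out <- rbind(out, p)
  }
  out
}

eval_metric <- function(net, set, cfg) {
  probs <- predict_probs(net, set$volumes, cfg$batch_size)
  labels <- dataset_labels(set, cfg$task)
  if (cfg$task == "age_bins") {
    pred <- decode_age(probs, cfg$bins)
    mean(abs(pred - labels))
  } else {
    mean((probs[, 2] > 0.5) == (labels == 1))
  }
}

snapshot_state <- function(net) {
  layers <- collect_param_layers(net)
  list(params = snapshot_params(net),
       buffers = lapply(layers, function(l)
         if (inherits(l, "norm3d_layer"))
           list(running_mean = l$running_mean, running_var = l$running_var)))
}

restore_state <- function(net, state) {
  restore_params(net, state$params)
  layers <- collect_param_layers(net)
  for (i in seq_along(layers)) {
    if (!is.null(state$buffers[[i]])) {
      layers[[i]]$running_mean <- state$buffers[[i]]$running_mean
      layers[[i]]$running_var <- state$buffers[[i]]$running_var
    }
  }
  invisible(net)
}

#' Train a network
#'
#' Mini-batch gradient descent on the soft-classification loss (KL
#' divergence against Gaussian soft labels for the age task, cross-entropy
#' for the binary sex task), with augmentation applied to training volumes
#' only. Validation is evaluated after every epoch on unaugmented data in
#' inference mode; the parameters of the epoch with the best validation
#' metric (lowest MAE, or highest accuracy for the sex task; ties go to the
#' earliest epoch) are restored into the returned model. Given the same
#' seed, configuration and initial weights, training is deterministic.
#'
#' @param net a network from [build_sfcn()] (its `task` should match
#'   `cfg$task`).
#' @param train_set,val_set [volume_dataset()]s with the labels the task
#'   needs.
#' @param cfg a [train_config()].
#' @return an object of class `sfcn_fit`: the trained network (best epoch),
#'   the per-epoch `history` data frame (`epoch`, `lr`, `train_loss`, train
#'   and validation metric), `best_epoch`, the validation
#'   [prediction_records()] at the best epoch, and the configuration.
#' @export
sfcn_train <- function(net, train_set, val_set, cfg) {
  stopifnot(inherits(net, "cnn_network"), inherits(cfg, "train_config"),
            inherits(train_set, "volume_dataset"),
            inherits(val_set, "volume_dataset"))
  if (length(train_set) == 0L) stop("empty training set")
  labels <- dataset_labels(train_set, cfg$task)
  targets <- make_targets(labels, cfg)
  n <- length(train_set)
  C <- nrow(targets)

  history <- NULL
  best_metric <- if (cfg$task == "age_bins") Inf else -Inf
  best_epoch <- NA_integer_
  best_state <- NULL

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$total_epochs)) {
      lr <- lr_at_epoch(cfg, epoch)
      ord <- sample.int(n)
      epoch_loss <- 0; nb <- 0L
      train_pred <- numeric(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        B <- length(idx)
        vols <- lapply(train_set$volumes[idx], augment_volume, cfg$augment)
        x <- stack_volumes(vols)
        p <- network_forward(net, x, training = TRUE)   # B x C
        tmat <- targets[, idx, drop = FALSE]            # C x B
        loss <- mean(vapply(seq_len(B), function(i)
          kl_loss(p[i, ], tmat[, i]), numeric(1)))
        dz <- (t(p) - tmat) / B                         # C x B
        dim(dz) <- c(1L, 1L, 1L, C, B)
        zero_grads(net)
        layer_backward(net$module, dz)
        if (cfg$optimizer == "sgd")
          sgd_step(net, lr, cfg$momentum, cfg$weight_decay)
        else
          adam_step(net, lr, weight_decay = cfg$weight_decay)
        epoch_loss <- epoch_loss + loss; nb <- nb + 1L
        train_pred[idx] <- if (cfg$task == "age_bins")
          decode_age(p, cfg$bins) else as.numeric(p[, 2] > 0.5)
      }
      train_metric <- if (cfg$task == "age_bins")
        mean(abs(train_pred - labels)) else mean(train_pred == labels)
      val_metric <- eval_metric(net, val_set, cfg)
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = epoch_loss / nb,
        train_metric = train_metric, val_metric = val_metric))
      if (cfg$verbose)
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  train %.3f  val %.3f",
                        epoch, lr, epoch_loss / nb, train_metric, val_metric))
      improved <- if (cfg$task == "age_bins") val_metric < best_metric
                  else val_metric > best_metric
      if (improved) {
        best_metric <- val_metric
        best_epoch <- epoch
        best_state <- snapshot_state(net)
      }
      if (!is.null(cfg$checkpoint_dir) && cfg$checkpoint_every > 0L &&
          epoch %% cfg$checkpoint_every == 0L) {
        dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        save_checkpoint(net, file.path(
          cfg$checkpoint_dir,
          sprintf("%s_epoch%d.ckpt", cfg$run_name, epoch)))
      }
    }
  })
  names(history)[names(history) == "train_metric"] <-
    if (cfg$task == "age_bins") "train_mae" else "train_accuracy"
  names(history)[names(history) == "val_metric"] <-
    if (cfg$task == "age_bins") "val_mae" else "val_accuracy"
  attr(history, "task") <- cfg$task

  if (!is.null(best_state)) restore_state(net, best_state)
  val_probs <- predict_probs(net, val_set$volumes, cfg$batch_size)
  val_labels <- dataset_labels(val_set, cfg$task)
  val_records <- if (cfg$task == "age_bins")
    prediction_records(val_set$id, val_labels,
                       decode_age(val_probs, cfg$bins))
  else prediction_records(val_set$id, val_labels,
                          as.numeric(val_probs[, 2] > 0.5))
  structure(list(network = net, history = history, config = cfg,
                 best_epoch = best_epoch, best_val_metric = best_metric,
                 val_records = val_records, bins = cfg$bins,
                 task = cfg$task),
            class = "sfcn_fit")
}

#' Select the best epoch from a training history
#'
#' The epoch with the lowest validation MAE (age task) or the highest
#' validation accuracy (sex task); ties resolve to the earliest epoch.
#'
#' @param history the `history` data frame of an [sfcn_train()] fit.
#' @return the 1-based epoch number.
#' @export
select_best_epoch <- function(history) {
  if (is.null(history) || nrow(history) == 0L) stop("empty history")
  if ("val_mae" %in% names(history))
    history$epoch[which.min(history$val_mae)]
  else if ("val_accuracy" %in% names(history))
    history$epoch[which.max(history$val_accuracy)]
  else stop("history has no validation metric column")
}

#' Training-metric statistics over an epoch window
#'
#' The overfitting summary convention: mean and SD of the training metric
#' over a late-epoch window, and the mean validation-train gap over the same
#' window.
#'
#' @param history the `history` data frame of an [sfcn_train()] fit.
#' @param from,to inclusive epoch window.
#' @return a list with `train_mean`, `train_sd` and `gap_mean` (validation
#'   minus train, in the metric's units).
#' @export
epoch_window_stats <- function(history, from, to) {
  rows <- history[history$epoch >= from & history$epoch <= to, ]
  if (nrow(rows) == 0L) stop("no epochs in window [", from, ", ", to, "]")
  tr_col <- intersect(c("train_mae", "train_accuracy"), names(rows))[1]
  va_col <- intersect(c("val_mae", "val_accuracy"), names(rows))[1]
  list(train_mean = mean(rows[[tr_col]]), train_sd = sd(rows[[tr_col]]),
       gap_mean = mean(rows[[va_col]] - rows[[tr_col]]))
}

#' Epoch count matched on total training steps
#'
#' When the training-set size changes, the epoch count is scaled so that the
#' total number of optimizer steps stays roughly the same.
#'
#' @param epochs_ref reference epoch count.
#' @param n_ref reference training-set size.
#' @param n_new new training-set size.
#' @return the matched epoch count (at least 1).
#' @export
steps_matched_epochs <- function(epochs_ref, n_ref, n_new) {
  max(1L, as.integer(round(epochs_ref * n_ref / n_new)))
}
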