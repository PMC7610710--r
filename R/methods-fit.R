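# S3 methods for fitted models.

#' @export
print.sfcn_fit <- function(x, ...) {
  cat("<sfcn_fit>\n")
  cat(sprintf("  task: %s   epochs: %d   best epoch: %d (val %s = %.3f)\n",
              x$task, nrow(x$history), x$best_epoch,
              if (x$task == "age_bins") "MAE" else "accuracy",
              x$best_val_metric))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x$network), big.mark = ",")))
  invisible(x)
}

#' @export
summary.sfcn_fit <- function(object, ...) {
  h <- object$history
  cat("Training summary\n")
  print(object)
  cat("\nFinal epochs:\n")
  print(utils::tail(h, 3), row.names = FALSE)
  if (object$task == "age_bins" && nrow(object$val_records) >= 3) {
    cat(sprintf("\nValidation (best epoch): MAE %.3f y, Pearson r %.3f\n",
                mae(object$val_records), pearson_r(object$val_records)))
  }
  invisible(object)
}

#' Predict from a fitted network
#'
#' @param object an [sfcn_train()] fit.
#' @param newdata a [volume_dataset()], a list of 3D arrays, or a single 3D
#'   array.
#' @param type `"age"` (decoded years; class 0/1 for the sex task),
#'   `"probs"` (the full probability matrix) or `"records"`
#'   ([prediction_records()], requires labels in `newdata`).
#' @param ... unused.
#' @return depends on `type`.
#' @export
predict.sfcn_fit <- function(object, newdata,
                             type = c("age", "probs", "records"), ...) {
  type <- match.arg(type)
  if (is.array(newdata) && length(dim(newdata)) == 3L)
    newdata <- volume_dataset(list(newdata))
  if (is.list(newdata) && !inherits(newdata, "volume_dataset") &&
      all(vapply(newdata, is.array, logical(1))))
    newdata <- volume_dataset(newdata)
  stopifnot(inherits(newdata, "volume_dataset"))
  probs <- predict_probs(object$network, newdata$volumes,
                         object$config$batch_size)
  if (type == "probs") return(probs)
  pred <- if (object$task == "age_bins") decode_age(probs, object$bins)
          else as.numeric(probs[, 2] > 0.5)
  if (type == "age") return(pred)
  labels <- dataset_labels(newdata, object$task)
  prediction_records(newdata$id, labels, pred)
}

#' @export
coef.sfcn_fit <- function(object, ...) snapshot_params(object$network)

#' Residuals of a fitted brain-age model
#'
#' The validation-set brain-age deltas (predicted minus true age) at the
#' selected best epoch.
#'
#' @param object an [sfcn_train()] fit.
#' @param ... unused.
#' @export
residuals.sfcn_fit <- function(object, ...) {
  setNames(object$val_records$delta, object$val_records$subject_id)
}

#' Plot training history
#'
#' Training and validation metric per epoch, with the selected best epoch
#' marked.
#'
#' @param x an [sfcn_train()] fit.
#' @param ... passed to [plot()].
#' @export
plot.sfcn_fit <- function(x, ...) {
  h <- x$history
  tr <- if (x$task == "age_bins") h$train_mae else h$train_accuracy
  va <- if (x$task == "age_bins") h$val_mae else h$val_accuracy
  ylab <- if (x$task == "age_bins") "MAE (years)" else "accuracy"
  plot(h$epoch, va, type = "l", col = "firebrick", xlab = "epoch",
       ylab = ylab, ylim = range(c(tr, va)), ...)
  lines(h$epoch, tr, col = "steelblue")
  abline(v = x$best_epoch, lty = 3)
  legend("topright", c("validation", "train"), lty = 1, bty = "n",
         col = c("firebrick", "steelblue"))
  invisible(x)
}

#' Simulate predictions from a fitted model
#'
#' Draws age predictions by sampling one age bin per subject from the
#' model's output distribution (rather than taking its expectation), which
#' is occasionally useful for uncertainty illustrations.
#'
#' @param object an [sfcn_train()] fit (age task).
#' @param nsim number of simulated prediction sets.
#' @param seed integer seed.
#' @param newdata a [volume_dataset()].
#' @param ... unused.
#' @return a matrix `length(newdata) x nsim` of sampled ages.
#' @export
simulate.sfcn_fit <- function(object, nsim = 1, seed = 1L, newdata, ...) {
  stopifnot(object$task == "age_bins")
  probs <- predict(object, newdata, type = "probs")
  centers <- object$bins$centers
  with_seed(seed, {
    vapply(seq_len(nsim), function(s)
      apply(probs, 1, function(p) sample(centers, 1L, prob = p)),
      numeric(nrow(probs)))
  })
}
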