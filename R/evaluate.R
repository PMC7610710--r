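# Prediction metrics: MAE, Pearson r between predicted and true age,
# Spearman correlation between the brain-age delta and age (the bias
# measure), and bootstrap uncertainty for any metric.

#' Assemble per-subject prediction records
#'
#' @param subject_id subject identifiers.
#' @param y true (chronological) ages in years.
#' @param x predicted ages (brain ages) in years.
#' @return a data frame of class `prediction_records` with columns
#'   `subject_id`, `y`, `x` and `delta` (= `x - y`, the brain-age delta);
#'   `corrected_x` and `corrected_delta` are added by [apply_correction()].
#' @export
prediction_records <- function(subject_id, y, x) {
  stopifnot(length(y) == length(x))
  if (missing(subject_id) || is.null(subject_id))
    subject_id <- sprintf("sub-%d", seq_along(y))
  out <- data.frame(subject_id = as.character(subject_id),
                    y = as.numeric(y), x = as.numeric(x),
                    delta = as.numeric(x) - as.numeric(y),
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_records", "data.frame")
  out
}

records_xy <- function(records, x = NULL) {
  if (is.data.frame(records)) {
    stopifnot(all(c("x", "y") %in% names(records)))
    list(x = records$x, y = records$y)
  } else {
    stopifnot(!is.null(x), length(records) == length(x))
    list(x = x, y = records)  # (y, x) vector form
  }
}

#' Mean absolute error
#'
#' `MAE = (1/N) sum |x_i - y_i|` in years. Invariant to adding a common
#' constant to both predictions and truths.
#'
#' @param records a [prediction_records()] data frame, or a numeric vector of
#'   true ages (then `x` must hold the predictions).
#' @param x predicted ages when `records` is a plain vector.
#' @return MAE in years.
#' @export
mae <- function(records, x = NULL) {
  v <- records_xy(records, x)
  if (length(v$x) < 1L) stop("empty prediction set")
  mean(abs(v$x - v$y))
}

#' Pearson correlation between predicted and true age
#'
#' @inheritParams mae
#' @return the sample Pearson r in `[-1, 1]`.
#' @export
pearson_r <- function(records, x = NULL) {
  v <- records_xy(records, x)
  if (length(v$x) < 3L) stop("need at least 3 records")
  if (sd(v$x) == 0 || sd(v$y) == 0)
    stop("degenerate variance: correlation undefined")
  cor(v$x, v$y)
}

#' Spearman correlation between brain-age delta and age
#'
#' The standard measure of prediction bias: an ideal predictor has delta
#' independent of age (correlation near zero), while regression toward the
#' cohort mean produces a negative correlation. Ties receive average ranks;
#' the statistic is invariant to strictly monotone transforms of delta.
#'
#' @param records a [prediction_records()] data frame (uses `delta` and `y`),
#'   or a numeric vector of ages with `x` the deltas.
#' @param x deltas when `records` is a plain vector of ages.
#' @return Spearman rho in `[-1, 1]`.
#' @export
spearman_delta_age <- function(records, x = NULL) {
  if (is.data.frame(records)) {
    delta <- records$delta; y <- records$y
  } else {
    y <- records; delta <- x
  }
  if (length(y) < 3L) stop("need at least 3 records")
  if (diff(range(delta)) <= 1e-10 * max(1, abs(mean(delta))) ||
      diff(range(y)) <= 1e-10 * max(1, abs(mean(y))))
    stop("degenerate ranks: Spearman correlation undefined")
  cor(delta, y, method = "spearman")
}

#' Bootstrap mean and standard deviation of a metric
#'
#' Resamples subjects (rows) with replacement `n_boot` times and reports the
#' mean and standard deviation of the metric across resamples — the
#' uncertainty convention used for test MAEs here.
#'
#' @param records a [prediction_records()] data frame.
#' @param metric a function of a records data frame returning a scalar
#'   (default [mae()]).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed (the session RNG is left untouched).
#' @return a list with `mean`, `sd` and `n_boot`.
#' @export
bootstrap_metric <- function(records, metric = mae, n_boot = 1000L,
                             seed = 1L) {
  stopifnot(is.data.frame(records), nrow(records) >= 2L)
  n <- nrow(records)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      metric(records[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
  })
  list(mean = mean(vals), sd = sd(vals), n_boot = n_boot)
}
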