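# Brain-age delta bias correction. Predictions regress toward the cohort
# mean (regression dilution, non-Gaussian label distributions), so the delta
# correlates negatively with age. The remedy: fit x = a*y + b on a labeled
# validation set, then invert it, x_hat = (x - b) / a, on any other set --
# including one whose true ages are unknown, assuming a and b generalize.

#' Fit the prediction-on-age bias model
#'
#' Ordinary least squares of predicted age `x` on chronological age `y`
#' (`x = a*y + b`) on a labeled set, typically the left-out validation set.
#' The fitted slope and intercept are then transferred unchanged to the test
#' set by [apply_correction()]; they are never silently refitted.
#'
#' @param records a [prediction_records()] data frame, or a numeric vector of
#'   true ages (then `x` must hold the predictions).
#' @param x predicted ages when `records` is a plain vector.
#' @param fit_set_id optional label recording which set the model was fitted
#'   on.
#' @return an object of class `bias_model` with fields `a` (slope), `b`
#'   (intercept, years), `fit_n` and `fit_set_id`.
#' @examples
#' y <- runif(100, 42, 82)
#' fit_bias(prediction_records(NULL, y, 0.8 * y + 10))  # a = 0.8, b = 10
#' @export
fit_bias <- function(records, x = NULL, fit_set_id = "") {
  v <- records_xy(records, x)
  if (length(v$y) < 3L) stop("need at least 3 records to fit the bias model")
  if (var(v$y) == 0) stop("degenerate true ages: no variance in y")
  fit <- lm(x ~ y, data = data.frame(x = v$x, y = v$y))
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  if (abs(a) < 1e-6)
    stop("fitted slope is ", signif(a, 3),
         "; the correction x_hat = (x - b)/a is not invertible")
  structure(list(a = a, b = b, fit_n = length(v$y),
                 fit_set_id = fit_set_id),
            class = "bias_model")
}

#' Apply a fitted bias correction
#'
#' Corrected predicted age is `x_hat = (x - b) / a`. Only the predictions are
#' needed — no knowledge of the subjects' true ages — so the correction
#' transfers to unlabeled test sets. The map is strictly monotone, hence the
#' ranking of subjects by predicted age is preserved.
#'
#' @param x predicted ages (numeric), or a [prediction_records()] data frame,
#'   in which case columns `corrected_x` and `corrected_delta` are filled.
#' @param model a [fit_bias()] model.
#' @return corrected ages, or the records data frame with corrected columns.
#' @export
apply_correction <- function(x, model) {
  stopifnot(inherits(model, "bias_model"))
  if (model$a == 0) stop("slope a is zero")
  if (is.data.frame(x)) {
    x$corrected_x <- (x$x - model$b) / model$a
    x$corrected_delta <- x$corrected_x - x$y
    return(x)
  }
  (x - model$b) / model$a
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("<bias_model> x = %.4f * y + %.3f  (fit on n = %d%s)\n",
              x$a, x$b, x$fit_n,
              if (nzchar(x$fit_set_id)) paste0(", ", x$fit_set_id) else ""))
  cat("  correction: x_hat = (x - b) / a\n")
  invisible(x)
}

#' @export
coef.bias_model <- function(object, ...)
  c(slope = object$a, intercept = object$b)

#' @export
predict.bias_model <- function(object, x, ...) apply_correction(x, object)
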