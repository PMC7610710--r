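# Model ensembling across replicates and pseudo-modalities, plus the
# diagnostics explaining why averaging helps: the less correlated two
# models' delta vectors are, the more their errors cancel.

check_prediction_matrix <- function(pm) {
  pm <- as.matrix(pm)
  if (anyNA(pm)) stop("prediction matrix must have no missing entries")
  pm
}

#' Ensemble prediction by averaging
#'
#' The final prediction for each subject is the arithmetic mean of the
#' selected models' predicted ages (row-wise mean).
#'
#' @param pm prediction matrix: rows = subjects, columns = models, entries =
#'   predicted ages in years; all columns share the same subject ordering.
#' @param columns column indices or names to average over (default: all).
#' @return per-subject ensemble predictions.
#' @export
ensemble_mean <- function(pm, columns = NULL) {
  pm <- check_prediction_matrix(pm)
  if (is.null(columns)) columns <- seq_len(ncol(pm))
  if (length(columns) == 0L) stop("empty model subset")
  rowMeans(pm[, columns, drop = FALSE])
}

#' Correlation matrix of per-model brain-age deltas
#'
#' Pearson correlations between the delta vectors (`x_col - y`) of every
#' pair of models: symmetric with unit diagonal. Models trained on the same
#' modality tend to correlate more strongly than models trained on different
#' modalities.
#'
#' @param pm prediction matrix (see [ensemble_mean()]).
#' @param y true ages, one per subject.
#' @return a K x K correlation matrix.
#' @export
delta_correlation_matrix <- function(pm, y) {
  pm <- check_prediction_matrix(pm)
  if (ncol(pm) < 2L) stop("need at least 2 models")
  stopifnot(nrow(pm) == length(y))
  deltas <- pm - y
  sds <- apply(deltas, 2, sd)
  if (any(sds == 0)) stop("degenerate delta variance in column(s): ",
                          paste(which(sds == 0), collapse = ", "))
  cor(deltas)
}

#' Pairwise ensemble improvement versus delta correlation
#'
#' For every unordered pair of models, computes the MAE improvement of the
#' two-model average over the pair's mean single-model MAE, together with
#' the Pearson correlation of the pair's deltas. Across pairs, improvement
#' tends to decrease as delta correlation increases: ensembling uncorrelated
#' models is what pays.
#'
#' @param pm prediction matrix (see [ensemble_mean()]).
#' @param y true ages, one per subject.
#' @return a data frame with columns `model_i`, `model_j`, `delta_cor`,
#'   `mae_i`, `mae_j`, `mae_pair`, `improvement`.
#' @export
pairwise_improvement <- function(pm, y) {
  pm <- check_prediction_matrix(pm)
  if (ncol(pm) < 2L) stop("need at least 2 models")
  stopifnot(nrow(pm) == length(y))
  K <- ncol(pm)
  nm <- colnames(pm)
  if (is.null(nm)) nm <- paste0("model", seq_len(K))
  maes <- apply(pm, 2, function(col) mean(abs(col - y)))
  deltas <- pm - y
  pairs <- utils::combn(K, 2)
  out <- data.frame(
    model_i = nm[pairs[1, ]], model_j = nm[pairs[2, ]],
    delta_cor = apply(pairs, 2, function(ij)
      cor(deltas[, ij[1]], deltas[, ij[2]])),
    mae_i = maes[pairs[1, ]], mae_j = maes[pairs[2, ]],
    mae_pair = apply(pairs, 2, function(ij)
      mean(abs(rowMeans(pm[, ij, drop = FALSE]) - y))),
    stringsAsFactors = FALSE, row.names = NULL)
  out$improvement <- (out$mae_i + out$mae_j) / 2 - out$mae_pair
  out
}
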