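# Age discretization, Gaussian soft labels, the KL training loss and the
# expected-value age decoder: the machinery that casts age regression as a
# soft classification problem.

#' Discretize an age range into bins
#'
#' Splits `[min_age, max_age]` into contiguous bins of width `bin_width`
#' years with centers at the interval midpoints. Both the one-year 42-82
#' grid and the two-year 14-94 grid yield 40 bins.
#'
#' @param min_age,max_age range in years; the difference must be an exact
#'   multiple of `bin_width`.
#' @param bin_width bin width in years.
#' @return an object of class `age_bins` with fields `min_age`, `max_age`,
#'   `bin_width`, `n_bins` and `centers`.
#' @examples
#' age_bins(42, 82, 1)$n_bins   # 40
#' age_bins(14, 94, 2)$centers  # 15, 17, ..., 93
#' @export
age_bins <- function(min_age, max_age, bin_width = 1) {
  if (max_age <= min_age) stop("max_age must exceed min_age")
  n <- (max_age - min_age) / bin_width
  if (abs(n - round(n)) > 1e-9)
    stop("(max_age - min_age) must be an exact multiple of bin_width")
  n <- as.integer(round(n))
  centers <- min_age + (seq_len(n) - 0.5) * bin_width
  structure(list(min_age = min_age, max_age = max_age,
                 bin_width = bin_width, n_bins = n, centers = centers),
            class = "age_bins")
}

#' @export
print.age_bins <- function(x, ...) {
  cat(sprintf("<age_bins> %d bins of %gy on [%g, %g]; centers %g ... %g\n",
              x$n_bins, x$bin_width, x$min_age, x$max_age,
              x$centers[1], x$centers[x$n_bins]))
  invisible(x)
}

#' Gaussian soft label over age bins
#'
#' The training target is not a one-hot age class but a discretized Gaussian
#' centered on the true age: the density is evaluated at each bin center and
#' renormalized to sum to one. This makes the loss decrease smoothly as the
#' predicted distribution moves toward the right age.
#'
#' @param true_age age(s) in years; a warning (not an error) is issued for
#'   ages outside the bin range.
#' @param bins an [age_bins()] object.
#' @param sigma Gaussian width in years (> 0); 1 year for one-year bins is
#'   the reference choice, and `bin_width` is a sensible default otherwise.
#' @return a probability vector of length `n_bins` (or a matrix with one
#'   column per age when `true_age` has length > 1), summing to one.
#' @examples
#' sl <- soft_label(62.5, age_bins(42, 82, 1), sigma = 1)
#' sl[21] / sl[20]  # exp(0.5): one half-bin closer to the mean
#' @export
soft_label <- function(true_age, bins, sigma = bins$bin_width) {
  stopifnot(inherits(bins, "age_bins"))
  if (sigma <= 0) stop("sigma must be positive")
  if (any(true_age < bins$min_age | true_age > bins$max_age))
    warning("true_age outside the bin range [", bins$min_age, ", ",
            bins$max_age, "]; label mass will pile at the boundary")
  one <- function(a) {
    logp <- -(bins$centers - a)^2 / (2 * sigma^2)
    p <- exp(logp - max(logp))
    p / sum(p)
  }
  if (length(true_age) == 1L) return(one(true_age))
  vapply(true_age, one, numeric(bins$n_bins))
}

#' Kullback-Leibler divergence loss
#'
#' `KL(target || output) = sum_c t_c log(t_c / x_c)`, the soft-classification
#' training loss: non-negative, and zero exactly when the predicted
#' distribution equals the target. Output probabilities are clamped at
#' 1e-12 before taking logarithms.
#'
#' @param output predicted probability vector (network softmax output).
#' @param target soft-label probability vector of the same length.
#' @return a non-negative scalar.
#' @export
kl_loss <- function(output, target) {
  if (length(output) != length(target))
    stop("output and target lengths differ")
  x <- pmax(output, 1e-12)
  nz <- target > 0
  sum(target[nz] * (log(target[nz]) - log(x[nz])))
}

#' Decode a predicted age from bin probabilities
#'
#' The scalar prediction is the probability-weighted average of the bin
#' centers, `pred = sum_c x_c * age_c`; it always lies within
#' `[first center, last center]`.
#'
#' @param output a probability vector of length `n_bins`, or an `n x n_bins`
#'   matrix (one row per subject, as returned by [network_forward()]).
#' @param bins an [age_bins()] object.
#' @return predicted age(s) in years.
#' @examples
#' b <- age_bins(42, 82, 1)
#' decode_age(rep(1 / 40, 40), b)  # 62, the mid-range age
#' @export
decode_age <- function(output, bins) {
  stopifnot(inherits(bins, "age_bins"))
  if (is.matrix(output)) {
    if (ncol(output) != bins$n_bins) stop("output has wrong number of bins")
    return(as.numeric(output %*% bins$centers))
  }
  if (length(output) != bins$n_bins) stop("output has wrong number of bins")
  sum(output * bins$centers)
}

#' Binary cross-entropy loss for the sex-classification task
#'
#' For the two-class variant the soft-classification loss is replaced by
#' plain cross-entropy, `-log x_label`.
#'
#' @param output probability vector of length 2.
#' @param label class index, 0 or 1.
#' @return a non-negative scalar.
#' @export
binary_loss <- function(output, label) {
  if (length(output) != 2L) stop("binary_loss requires exactly 2 classes")
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  -log(pmax(output[label + 1L], 1e-12))
}
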