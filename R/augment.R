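# Training-time volumetric augmentation: small integer voxel shifts along
# every axis and mirroring about the sagittal plane. Both exploit the
# approximate translation- and left-right-symmetry of registered brains;
# neither is ever applied at validation or test time.

#' Augmentation configuration
#'
#' @param max_shift maximum voxel shift per axis; offsets are drawn uniformly
#'   from `{-max_shift, ..., +max_shift}` independently per axis (the shift
#'   magnitude of "0, 1 or 2 voxels" is made direction-symmetric so the brain
#'   is not biased off-center).
#' @param mirror_prob probability of mirroring about the sagittal plane.
#' @param enabled logical; with `FALSE` the training pipeline is bit-identical
#'   to an unaugmented run.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(max_shift = 2L, mirror_prob = 0.5, enabled = TRUE) {
  if (max_shift < 0) stop("max_shift must be >= 0")
  if (mirror_prob < 0 || mirror_prob > 1)
    stop("mirror_prob must be in [0, 1]")
  structure(list(max_shift = as.integer(max_shift),
                 mirror_prob = mirror_prob, enabled = isTRUE(enabled)),
            class = "augment_config")
}

#' Randomly shift a volume by whole voxels
#'
#' Translates the content by an independently drawn integer offset per axis,
#' uniform over `{-max_shift, ..., +max_shift}`; vacated voxels are filled
#' with zero (the background value after brain extraction). Shape is
#' preserved.
#'
#' @param volume a 3D array.
#' @param max_shift maximum shift in voxels (must be smaller than every
#'   dimension).
#' @param offset optional integer vector of length 3 forcing a specific
#'   offset (used for testing); `NULL` draws randomly.
#' @return a 3D array of the same shape.
#' @export
random_shift <- function(volume, max_shift = 2L, offset = NULL) {
  d <- dim(volume)
  if (length(d) != 3L) stop("volume must be a 3D array")
  if (max_shift >= min(d)) stop("max_shift must be smaller than every dimension")
  if (is.null(offset))
    offset <- sample.int(2L * max_shift + 1L, 3L, replace = TRUE) -
      (max_shift + 1L)
  offset <- as.integer(offset)
  if (all(offset == 0L)) return(volume)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- offset[a]
    src[[a]] <- if (o >= 0) 1:(d[a] - o) else (1 - o):d[a]
    dst[[a]] <- if (o >= 0) (1 + o):d[a] else 1:(d[a] + o)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- volume[src[[1]], src[[2]], src[[3]]]
  out
}

#' Mirror a volume about the sagittal plane
#'
#' With probability `prob`, reverses the left-right axis (axis 1 under the
#' canonical orientation enforced by [load_volume()]); otherwise returns the
#' input unchanged. Applying a forced mirror twice is the identity.
#'
#' @param volume a 3D array in canonical (left-right first) orientation.
#' @param prob mirroring probability.
#' @param force `TRUE`/`FALSE` to force the decision (testing); `NULL` draws
#'   randomly.
#' @return a 3D array of the same shape.
#' @export
sagittal_mirror <- function(volume, prob = 0.5, force = NULL) {
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  do_it <- if (is.null(force)) runif(1) < prob else isTRUE(force)
  if (!do_it) return(volume)
  volume[dim(volume)[1]:1, , , drop = FALSE]
}

# Apply the configured augmentations to one training volume.
augment_volume <- function(volume, cfg) {
  if (!cfg$enabled) return(volume)
  volume <- random_shift(volume, cfg$max_shift)
  sagittal_mirror(volume, cfg$mirror_prob)
}
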