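#' Specification of the Simple Fully Convolutional Network
#'
#' The SFCN is a seven-block 3D CNN for volumetric single-channel images.
#' Blocks 1-5 are feature extractors (3x3x3 convolution, normalization,
#' 2x2x2 max pooling, ReLU), block 6 is a 1x1x1 convolutional bottleneck
#' (convolution, normalization, ReLU), and block 7 maps features to class
#' probabilities (global average pooling, dropout, 1x1x1 convolution,
#' softmax). With the default channel widths `[32, 64, 128, 256, 256, 64,
#' 40]` and a 40-bin head the model has 2,952,936 trainable parameters
#' (about 3.0 million).
#'
#' @param channel_widths integer vector of length 7: output channels of the
#'   five extractor blocks, the bottleneck block, and the output layer. The
#'   last entry must equal `n_output`.
#' @param input_shape three positive integers, the expected volume shape in
#'   voxels. Each dimension must be divisible by 32 (five halving pool
#'   stages) unless `adaptive_pool = TRUE`.
#' @param n_output number of output units (age bins, or 2 for binary sex
#'   classification).
#' @param dropout_rate dropout fraction in block 7 (training only).
#' @param norm_kind `"batch"` or `"instance"` normalization; both carry
#'   learnable affine terms and are drop-in replacements.
#' @param task `"age_bins"` or `"sex_binary"`.
#' @param adaptive_pool allow input shapes not divisible by 32; the global
#'   average pool in block 7 absorbs whatever spatial grid remains, so any
#'   input with all dimensions >= 32 works.
#' @return an object of class `sfcn_spec`.
#' @seealso [build_sfcn()], [sfcn_shape_trace()]
#' @export
sfcn_spec <- function(channel_widths = c(32L, 64L, 128L, 256L, 256L, 64L, 40L),
                      input_shape = c(160L, 192L, 160L),
                      n_output = 40L,
                      dropout_rate = 0.5,
                      norm_kind = c("batch", "instance"),
                      task = c("age_bins", "sex_binary"),
                      adaptive_pool = FALSE) {
  norm_kind <- match.arg(norm_kind)
  task <- match.arg(task)
  channel_widths <- as.integer(channel_widths)
  input_shape <- as.integer(input_shape)
  n_output <- as.integer(n_output)
  if (length(channel_widths) != 7L)
    stop("channel_widths must have exactly 7 entries ",
         "(5 extractor blocks + bottleneck + output width)")
  if (any(channel_widths < 1L)) stop("channel widths must be positive")
  if (channel_widths[7L] != n_output)
    stop("last channel width (", channel_widths[7L],
         ") must equal n_output (", n_output, ")")
  if (length(input_shape) != 3L || any(input_shape < 1L))
    stop("input_shape must be 3 positive integers")
  if (!adaptive_pool && any(input_shape %% 32L != 0L))
    stop("each input dimension must be divisible by 2^5 = 32; ",
         "set adaptive_pool = TRUE to accept other shapes")
  if (adaptive_pool && any(input_shape < 32L))
    stop("all input dimensions must be at least 32")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]")
  structure(list(channel_widths = channel_widths, input_shape = input_shape,
                 n_output = n_output, dropout_rate = dropout_rate,
                 norm_kind = norm_kind, task = task,
                 adaptive_pool = adaptive_pool),
            class = "sfcn_spec")
}

#' Per-block shape trace of the SFCN
#'
#' Computes the spatial shape of the feature map emitted by each block for a
#' given input shape. Convolutions are shape-preserving (3x3x3, stride 1,
#' padding 1); each of the five max-pool stages floor-halves every axis; the
#' block-7 global average pool reduces to 1x1x1. For the default
#' 160x192x160 input the block-5 feature map is 5x6x5.
#'
#' @param spec an [sfcn_spec()].
#' @param input_shape optional shape overriding `spec$input_shape`.
#' @return a 7 x 3 integer matrix of per-block output spatial shapes.
#' @export
sfcn_shape_trace <- function(spec, input_shape = NULL) {
  d <- as.integer(if (is.null(input_shape)) spec$input_shape else input_shape)
  out <- matrix(NA_integer_, 7L, 3L,
                dimnames = list(paste0("block", 1:7), c("d1", "d2", "d3")))
  for (b in 1:5) {
    d <- d %/% 2L
    out[b, ] <- d
  }
  out[6L, ] <- d
  out[7L, ] <- c(1L, 1L, 1L)
  out
}

#' Build the Simple Fully Convolutional Network
#'
#' Instantiates the seven-block SFCN described in [sfcn_spec()]. Weights are
#' He-initialized from the current R random stream (pass `seed` for a
#' self-contained reproducible initialization). Dropout is active only in
#' training mode, so repeated inference passes on the same input are
#' identical.
#'
#' @param spec an [sfcn_spec()].
#' @param seed optional integer; when given, initialization uses a local RNG
#'   seeded with it and the session RNG is left untouched.
#' @return a `cnn_network` whose [network_forward()] maps a batch of
#'   single-channel volumes to an `n x n_output` matrix of probabilities.
#' @examples
#' spec <- sfcn_spec(input_shape = c(32, 32, 32),
#'                   channel_widths = c(4, 8, 8, 8, 8, 8, 10), n_output = 10)
#' net <- build_sfcn(spec, seed = 1)
#' p <- network_forward(net, array(rnorm(32^3), c(32, 32, 32)))
#' rowSums(p)  # 1
#' @export
build_sfcn <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sfcn_spec"))
  build <- function() {
    w <- spec$channel_widths
    layers <- list()
    cin <- 1L
    for (b in 1:5) {
      layers <- c(layers, list(
        conv3d_layer(cin, w[b], kernel = 3L, stride = 1L, pad = 1L,
                     bias = TRUE, input_grad = b > 1L),
        norm3d_layer(w[b], spec$norm_kind),
        maxpool3d_layer(2L, 2L, 0L),
        relu_layer()))
      cin <- w[b]
    }
    layers <- c(layers, list(
      conv3d_layer(cin, w[6L], kernel = 1L, stride = 1L, pad = 0L),
      norm3d_layer(w[6L], spec$norm_kind),
      relu_layer(),
      global_avgpool_layer(),
      dropout_layer(spec$dropout_rate),
      conv3d_layer(w[6L], w[7L], kernel = 1L, stride = 1L, pad = 0L)))
    new_cnn_network(nn_sequential(layers), spec, "sfcn", spec$task)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}
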