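#' Specification of a 3D residual network
#'
#' Comparison models: the standard residual-network recipe with every
#' convolution kernel made cubic. Depth 18 uses basic blocks (two 3x3x3
#' convolutions); depths 50/101/152 use bottleneck blocks (1x1x1 - 3x3x3 -
#' 1x1x1 with 4x expansion). The stem is a 7x7x7 stride-2 convolution
#' followed by 3x3x3 stride-2 max pooling; downsampling shortcuts are 1x1x1
#' strided convolutions with normalization; convolutions followed by a
#' normalization layer carry no bias. With one input channel and a 40-way
#' head this yields 33,180,520 parameters at depth 18 (33.2 million) and
#' 46,237,032 at depth 50 (46.2 million).
#'
#' @param depth one of 18, 50, 101, 152.
#' @param n_input_channels number of input channels (1 for T1 volumes).
#' @param n_output number of output units.
#' @return an object of class `resnet3d_spec`.
#' @export
resnet3d_spec <- function(depth = 18L, n_input_channels = 1L,
                          n_output = 40L) {
  depth <- as.integer(depth)
  if (!depth %in% c(18L, 50L, 101L, 152L))
    stop("unsupported depth: ", depth, " (choose 18, 50, 101 or 152)")
  structure(list(depth = depth,
                 n_input_channels = as.integer(n_input_channels),
                 n_output = as.integer(n_output)),
            class = "resnet3d_spec")
}

resnet3d_stage_blocks <- function(depth) {
  switch(as.character(depth),
         "18" = c(2L, 2L, 2L, 2L),
         "50" = c(3L, 4L, 6L, 3L),
         "101" = c(3L, 4L, 23L, 3L),
         "152" = c(3L, 8L, 36L, 3L))
}

basic_block3d <- function(cin, width, stride, norm_kind = "batch") {
  main <- list(
    conv3d_layer(cin, width, 3L, stride, 1L, bias = FALSE),
    norm3d_layer(width, norm_kind),
    relu_layer(),
    conv3d_layer(width, width, 3L, 1L, 1L, bias = FALSE),
    norm3d_layer(width, norm_kind))
  shortcut <- if (stride != 1L || cin != width)
    list(conv3d_layer(cin, width, 1L, stride, 0L, bias = FALSE),
         norm3d_layer(width, norm_kind))
  residual_block(main, shortcut)
}

bottleneck_block3d <- function(cin, mid, stride, norm_kind = "batch") {
  cout <- 4L * mid
  main <- list(
    conv3d_layer(cin, mid, 1L, 1L, 0L, bias = FALSE),
    norm3d_layer(mid, norm_kind),
    relu_layer(),
    conv3d_layer(mid, mid, 3L, stride, 1L, bias = FALSE),
    norm3d_layer(mid, norm_kind),
    relu_layer(),
    conv3d_layer(mid, cout, 1L, 1L, 0L, bias = FALSE),
    norm3d_layer(cout, norm_kind))
  shortcut <- if (stride != 1L || cin != cout)
    list(conv3d_layer(cin, cout, 1L, stride, 0L, bias = FALSE),
         norm3d_layer(cout, norm_kind))
  residual_block(main, shortcut)
}

#' Build a 3D residual network
#'
#' @param spec a [resnet3d_spec()], or a depth given directly.
#' @param seed optional integer for a self-contained reproducible
#'   initialization.
#' @return a `cnn_network`; [network_forward()] returns softmax
#'   probabilities.
#' @examples
#' count_parameters(build_resnet3d(resnet3d_spec(18), seed = 1))  # 33180520
#' @export
build_resnet3d <- function(spec, seed = NULL) {
  if (is.numeric(spec)) spec <- resnet3d_spec(spec)
  stopifnot(inherits(spec, "resnet3d_spec"))
  build <- function() {
    widths <- c(64L, 128L, 256L, 512L)
    blocks <- resnet3d_stage_blocks(spec$depth)
    bottleneck <- spec$depth >= 50L
    layers <- list(
      conv3d_layer(spec$n_input_channels, 64L, 7L, 2L, 3L, bias = FALSE,
                   input_grad = FALSE),
      norm3d_layer(64L, "batch"),
      relu_layer(),
      maxpool3d_layer(3L, 2L, 1L))
    cin <- 64L
    for (s in 1:4) {
      for (b in seq_len(blocks[s])) {
        stride <- if (b == 1L && s > 1L) 2L else 1L
        if (bottleneck) {
          layers <- c(layers,
                      list(bottleneck_block3d(cin, widths[s], stride)))
          cin <- 4L * widths[s]
        } else {
          layers <- c(layers, list(basic_block3d(cin, widths[s], stride)))
          cin <- widths[s]
        }
      }
    }
    layers <- c(layers, list(
      global_avgpool_layer(),
      conv3d_layer(cin, spec$n_output, 1L, 1L, 0L, bias = TRUE)))
    new_cnn_network(nn_sequential(layers), spec, "resnet3d")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}
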