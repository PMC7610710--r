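# Neural-network primitives for volumetric (3D) data.
#
# Activations are 5D arrays [d1, d2, d3, channels, batch] in R's column-major
# layout. Each layer is an environment carrying its parameters (`W`, `b`,
# `gamma`, `beta`), their gradient accumulators (prefix `g`), and a cache for
# backpropagation. Layers implement the generics `layer_forward`,
# `layer_backward` and `layer_param_names`.

new_layer <- function(kind, class) {
  l <- new.env(parent = emptyenv())
  l$kind <- kind
  l$trainable <- TRUE
  class(l) <- c(class, "nn_layer")
  l
}

layer_forward <- function(layer, x, training = FALSE) UseMethod("layer_forward")
layer_backward <- function(layer, grad) UseMethod("layer_backward")
layer_param_names <- function(layer) UseMethod("layer_param_names")

#' @export
layer_param_names.default <- function(layer) character(0)

as_tensor5 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array")
  if (length(d) == 3L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 4L) dim(x) <- c(d, 1L)
  else if (length(d) != 5L) stop("input must be a 3D, 4D or 5D array")
  x
}

# He-style initialization: weights ~ N(0, sqrt(2 / fan_in)), biases zero.
init_conv_weights <- function(k, cin, cout) {
  fan_in <- k^3 * cin
  array(rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)), c(k, k, k, cin, cout))
}

## ---- 3D convolution ---------------------------------------------------

conv3d_layer <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L,
                         bias = TRUE, input_grad = TRUE) {
  l <- new_layer("conv3d", "conv3d_layer")
  l$kernel <- as.integer(kernel); l$stride <- as.integer(stride)
  l$pad <- as.integer(pad)
  l$in_ch <- as.integer(in_ch); l$out_ch <- as.integer(out_ch)
  l$W <- init_conv_weights(l$kernel, in_ch, out_ch)
  l$b <- if (bias) numeric(out_ch) else NULL
  l$input_grad <- input_grad
  l
}

#' @export
layer_forward.conv3d_layer <- function(layer, x, training = FALSE) {
  if (training) layer$cache_x <- x
  .conv3d_fwd(x, layer$W, layer$b, layer$stride, layer$pad)
}

#' @export
layer_backward.conv3d_layer <- function(layer, grad) {
  res <- .conv3d_bwd(layer$cache_x, layer$W, grad, layer$stride, layer$pad,
                     layer$input_grad, !is.null(layer$b))
  layer$gW <- if (is.null(layer$gW)) res$dW else layer$gW + res$dW
  if (!is.null(layer$b))
    layer$gb <- if (is.null(layer$gb)) res$db else layer$gb + res$db
  layer$cache_x <- NULL
  res$dx
}

#' @export
layer_param_names.conv3d_layer <- function(layer)
  if (is.null(layer$b)) "W" else c("W", "b")

## ---- normalization ----------------------------------------------------

# Channel-wise normalization with learnable affine terms. kind = "batch"
# normalizes over (voxels x batch) per channel and keeps running statistics
# for inference; kind = "instance" normalizes each (channel, sample) over its
# voxels in both training and inference.
norm3d_layer <- function(ch, kind = c("batch", "instance"), eps = 1e-5,
                         momentum = 0.1) {
  kind <- match.arg(kind)
  l <- new_layer(paste0(kind, "norm3d"), "norm3d_layer")
  l$norm_kind <- kind
  l$ch <- as.integer(ch); l$eps <- eps; l$momentum <- momentum
  l$gamma <- rep(1, ch); l$beta <- rep(0, ch)
  l$running_mean <- rep(0, ch); l$running_var <- rep(1, ch)
  l
}

#' @export
layer_forward.norm3d_layer <- function(layer, x, training = FALSE) {
  d <- dim(x); S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  xm <- matrix(x, S, C * N)
  if (layer$norm_kind == "batch") {
    if (training) {
      mu_cn <- .colMeans(xm, S, C * N)
      m2_cn <- .colMeans(xm * xm, S, C * N)
      mu_c <- .rowMeans(matrix(mu_cn, C, N), C, N)
      var_c <- .rowMeans(matrix(m2_cn, C, N), C, N) - mu_c^2
      layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
        layer$momentum * mu_c
      layer$running_var <- (1 - layer$momentum) * layer$running_var +
        layer$momentum * var_c
    } else {
      mu_c <- layer$running_mean; var_c <- layer$running_var
    }
    mu_col <- rep(mu_c, N)
    invstd_col <- rep(1 / sqrt(var_c + layer$eps), N)
  } else {
    mu_col <- .colMeans(xm, S, C * N)
    invstd_col <- 1 / sqrt(.colMeans(xm * xm, S, C * N) - mu_col^2 + layer$eps)
  }
  xhat <- (xm - rep(mu_col, each = S)) * rep(invstd_col, each = S)
  g_col <- rep(layer$gamma, N); b_col <- rep(layer$beta, N)
  y <- xhat * rep(g_col, each = S) + rep(b_col, each = S)
  if (training) {
    layer$cache_xhat <- xhat
    layer$cache_invstd <- invstd_col
    layer$cache_dim <- d
  }
  dim(y) <- d
  y
}

#' @export
layer_backward.norm3d_layer <- function(layer, grad) {
  d <- layer$cache_dim; S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  dy <- matrix(grad, S, C * N)
  xhat <- layer$cache_xhat
  sum_dy_cn <- .colSums(dy, S, C * N)
  sum_dyx_cn <- .colSums(dy * xhat, S, C * N)
  dgamma <- .rowSums(matrix(sum_dyx_cn, C, N), C, N)
  dbeta <- .rowSums(matrix(sum_dy_cn, C, N), C, N)
  layer$ggamma <- if (is.null(layer$ggamma)) dgamma else layer$ggamma + dgamma
  layer$gbeta <- if (is.null(layer$gbeta)) dbeta else layer$gbeta + dbeta

  g_col <- rep(layer$gamma, N)
  if (layer$norm_kind == "batch") {
    m <- S * N
    mdy_c <- .rowSums(matrix(sum_dy_cn, C, N), C, N) / m
    mdyx_c <- .rowSums(matrix(sum_dyx_cn, C, N), C, N) / m
    mdy_col <- rep(mdy_c, N); mdyx_col <- rep(mdyx_c, N)
  } else {
    mdy_col <- sum_dy_cn / S; mdyx_col <- sum_dyx_cn / S
  }
  scale_col <- g_col * layer$cache_invstd
  dx <- (dy - rep(mdy_col, each = S) - xhat * rep(mdyx_col, each = S)) *
    rep(scale_col, each = S)
  layer$cache_xhat <- NULL
  dim(dx) <- d
  dx
}

#' @export
layer_param_names.norm3d_layer <- function(layer) c("gamma", "beta")

## ---- ReLU --------------------------------------------------------------

relu_layer <- function() new_layer("relu", "relu_layer")

#' @export
layer_forward.relu_layer <- function(layer, x, training = FALSE) {
  if (training) layer$cache_mask <- x > 0
  x * (x > 0)
}

#' @export
layer_backward.relu_layer <- function(layer, grad) {
  dx <- grad * layer$cache_mask
  layer$cache_mask <- NULL
  dx
}

## ---- max pooling -------------------------------------------------------

maxpool3d_layer <- function(kernel = 2L, stride = 2L, pad = 0L) {
  l <- new_layer("maxpool3d", "maxpool3d_layer")
  l$kernel <- as.integer(kernel); l$stride <- as.integer(stride)
  l$pad <- as.integer(pad)
  l
}

#' @export
layer_forward.maxpool3d_layer <- function(layer, x, training = FALSE) {
  res <- .maxpool3d_fwd(x, layer$kernel, layer$stride, layer$pad)
  if (training) {
    layer$cache_idx <- res$idx
    layer$cache_xdim <- dim(x)
  }
  res$y
}

#' @export
layer_backward.maxpool3d_layer <- function(layer, grad) {
  dx <- .maxpool3d_bwd(grad, layer$cache_idx, layer$cache_xdim)
  layer$cache_idx <- NULL
  dx
}

## ---- global average pooling --------------------------------------------

# Pools the entire remaining spatial grid to 1x1x1 per channel; this is what
# makes the architecture tolerant of varying input sizes.
global_avgpool_layer <- function() new_layer("global_avgpool", "gap_layer")

#' @export
layer_forward.gap_layer <- function(layer, x, training = FALSE) {
  d <- dim(x); S <- prod(d[1:3])
  y <- .colMeans(matrix(x, S, d[4] * d[5]), S, d[4] * d[5])
  if (training) layer$cache_dim <- d
  array(y, c(1L, 1L, 1L, d[4], d[5]))
}

#' @export
layer_backward.gap_layer <- function(layer, grad) {
  d <- layer$cache_dim; S <- prod(d[1:3])
  dx <- matrix(rep(as.numeric(grad), each = S) / S, S)
  dim(dx) <- d
  dx
}

## ---- dropout -----------------------------------------------------------

# Inverted dropout: active only in training mode, identity at inference.
dropout_layer <- function(rate = 0.5) {
  l <- new_layer("dropout", "dropout_layer")
  l$rate <- rate
  l
}

#' @export
layer_forward.dropout_layer <- function(layer, x, training = FALSE) {
  if (!training || layer$rate <= 0) return(x)
  mask <- (runif(length(x)) >= layer$rate) / (1 - layer$rate)
  dim(mask) <- dim(x)
  layer$cache_mask <- mask
  x * mask
}

#' @export
layer_backward.dropout_layer <- function(layer, grad) {
  if (is.null(layer$cache_mask)) return(grad)
  dx <- grad * layer$cache_mask
  layer$cache_mask <- NULL
  dx
}
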