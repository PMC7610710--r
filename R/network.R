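# Network containers, parameter bookkeeping and optimizer steps.
#
# A network is a tree of modules: the leaves are layers (layers.R), the
# internal nodes are `nn_sequential` chains and `residual_block`s. The
# classed wrapper `cnn_network` adds the softmax output contract: forward
# returns an N x C matrix of probabilities, one row per subject.

nn_sequential <- function(layers) {
  m <- new_layer("sequential", "nn_sequential")
  m$layers <- layers
  m
}

#' @export
layer_forward.nn_sequential <- function(layer, x, training = FALSE) {
  for (l in layer$layers) x <- layer_forward(l, x, training)
  x
}

#' @export
layer_backward.nn_sequential <- function(layer, grad) {
  for (l in rev(layer$layers)) grad <- layer_backward(l, grad)
  grad
}

# Residual block: y = relu(main(x) + shortcut(x)); the shortcut is either
# identity (NULL) or a projection (1x1x1 strided conv + norm).
residual_block <- function(main, shortcut = NULL) {
  m <- new_layer("residual", "residual_block")
  m$main <- nn_sequential(main)
  m$shortcut <- if (is.null(shortcut)) NULL else nn_sequential(shortcut)
  m
}

#' @export
layer_forward.residual_block <- function(layer, x, training = FALSE) {
  h <- layer_forward(layer$main, x, training)
  s <- if (is.null(layer$shortcut)) x
       else layer_forward(layer$shortcut, x, training)
  z <- h + s
  if (training) layer$cache_mask <- z > 0
  z * (z > 0)
}

#' @export
layer_backward.residual_block <- function(layer, grad) {
  dz <- grad * layer$cache_mask
  layer$cache_mask <- NULL
  dx <- layer_backward(layer$main, dz)
  if (is.null(layer$shortcut)) dx + dz
  else dx + layer_backward(layer$shortcut, dz)
}

# Depth-first list of every parameter-bearing layer in a module tree.
collect_param_layers <- function(module) {
  if (inherits(module, "nn_sequential"))
    return(unlist(lapply(module$layers, collect_param_layers)))
  if (inherits(module, "residual_block")) {
    out <- collect_param_layers(module$main)
    if (!is.null(module$shortcut))
      out <- c(out, collect_param_layers(module$shortcut))
    return(out)
  }
  if (inherits(module, "cnn_network"))
    return(collect_param_layers(module$module))
  if (length(layer_param_names(module))) list(module) else list()
}

#' Count trainable parameters of a network
#'
#' Sums the number of trainable scalars over every layer: convolution
#' weights and biases, affine normalization scales and offsets, and the
#' final classification head. Layers frozen with [set_trainable()] are
#' excluded.
#'
#' @param net a network built by [build_sfcn()] or [build_resnet3d()] (or
#'   any internal module).
#' @return integer count of trainable scalars.
#' @examples
#' net <- build_sfcn(sfcn_spec(input_shape = c(32, 32, 32),
#'                             channel_widths = c(4, 8, 8, 8, 8, 8, 10),
#'                             n_output = 10))
#' count_parameters(net)
#' @export
count_parameters <- function(net) {
  layers <- collect_param_layers(net)
  total <- 0
  for (l in layers) {
    if (!isTRUE(l$trainable)) next
    for (p in layer_param_names(l)) total <- total + length(l[[p]])
  }
  as.integer(total)
}

#' Freeze or unfreeze all parameters of a network
#'
#' @param net a network or module.
#' @param trainable logical; `FALSE` freezes every parameter so that
#'   [count_parameters()] reports 0 and optimizer steps skip them.
#' @return the network, invisibly (layers are modified in place).
#' @export
set_trainable <- function(net, trainable = TRUE) {
  for (l in collect_param_layers(net)) l$trainable <- isTRUE(trainable)
  invisible(net)
}

# Clear gradient accumulators before a new batch.
zero_grads <- function(net) {
  for (l in collect_param_layers(net)) {
    for (p in layer_param_names(l)) l[[paste0("g", p)]] <- NULL
  }
  invisible(net)
}

# SGD with momentum and coupled L2 weight decay:
#   g <- grad + wd * theta;  m <- mom * m + g;  theta <- theta - lr * m
sgd_step <- function(net, lr, momentum = 0.9, weight_decay = 0) {
  for (l in collect_param_layers(net)) {
    if (!isTRUE(l$trainable)) next
    for (p in layer_param_names(l)) {
      g <- l[[paste0("g", p)]]
      if (is.null(g)) next
      g <- g + weight_decay * l[[p]]
      mname <- paste0("m", p)
      m <- l[[mname]]
      m <- if (is.null(m)) g else momentum * m + g
      l[[mname]] <- m
      l[[p]] <- l[[p]] - lr * m
    }
  }
  invisible(net)
}

# Adam with framework-conventional defaults.
adam_step <- function(net, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  for (l in collect_param_layers(net)) {
    if (!isTRUE(l$trainable)) next
    for (p in layer_param_names(l)) {
      g <- l[[paste0("g", p)]]
      if (is.null(g)) next
      g <- g + weight_decay * l[[p]]
      tname <- paste0("t", p)
      l[[tname]] <- t_ <- (if (is.null(l[[tname]])) 0 else l[[tname]]) + 1
      m <- l[[paste0("am", p)]]; v <- l[[paste0("av", p)]]
      m <- if (is.null(m)) (1 - beta1) * g else beta1 * m + (1 - beta1) * g
      v <- if (is.null(v)) (1 - beta2) * g^2 else beta2 * v + (1 - beta2) * g^2
      l[[paste0("am", p)]] <- m; l[[paste0("av", p)]] <- v
      mhat <- m / (1 - beta1^t_); vhat <- v / (1 - beta2^t_)
      l[[p]] <- l[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(net)
}

# Snapshot / restore parameter values (used for best-epoch selection).
snapshot_params <- function(net)
  lapply(collect_param_layers(net), function(l)
    setNames(lapply(layer_param_names(l), function(p) l[[p]]),
             layer_param_names(l)))

restore_params <- function(net, snap) {
  layers <- collect_param_layers(net)
  stopifnot(length(layers) == length(snap))
  for (i in seq_along(layers)) {
    for (p in names(snap[[i]])) layers[[i]][[p]] <- snap[[i]][[p]]
  }
  # stale optimizer state must not leak into a restored model
  for (l in layers)
    for (p in layer_param_names(l))
      for (pre in c("m", "am", "av", "t")) l[[paste0(pre, p)]] <- NULL
  invisible(net)
}

## ---- classed network wrapper --------------------------------------------

new_cnn_network <- function(module, spec, arch, task = "age_bins") {
  net <- structure(new.env(parent = emptyenv()),
                   class = c(paste0(arch, "_network"), "cnn_network"))
  net$module <- module
  net$spec <- spec
  net$arch <- arch
  net$task <- task
  net
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(.colSums(e, nrow(e), ncol(e)), each = nrow(e))
}

#' Forward pass of a network
#'
#' Runs a batch of single-channel 3D volumes through the network and returns
#' the softmax output: one probability vector per subject, each non-negative
#' and summing to one.
#'
#' @param net a network from [build_sfcn()] or [build_resnet3d()].
#' @param x a 3D array (one volume), a list of 3D arrays, or a 5D array
#'   `[d1, d2, d3, 1, n]`.
#' @param training logical; `TRUE` enables dropout and batch statistics and
#'   caches activations for backpropagation.
#' @param logits logical; return pre-softmax scores instead of probabilities.
#' @return an `n x C` matrix (rows = subjects, columns = output bins).
#' @export
network_forward <- function(net, x, training = FALSE, logits = FALSE) {
  if (is.list(x)) x <- stack_volumes(x)
  x <- as_tensor5(x)
  z <- layer_forward(net$module, x, training)
  d <- dim(z)
  zm <- matrix(z, d[4], d[5])       # spatial is 1x1x1 after the head
  out <- if (logits) zm else softmax_cols(zm)
  t(out)
}

# Stack a list of equally-shaped 3D volumes into a [d, 1, n] tensor.
stack_volumes <- function(vols) {
  d <- dim(vols[[1]])
  x <- array(unlist(vols, use.names = FALSE), c(d, 1L, length(vols)))
  x
}

#' @export
print.cnn_network <- function(x, ...) {
  cat(sprintf("<%s network>  task: %s\n", x$arch, x$task))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
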