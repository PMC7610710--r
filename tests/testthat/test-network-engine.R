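# Correctness of the hand-written differentiation engine: every layer's
# analytic gradient is checked against central finite differences.

fd_layer_check <- function(make_layer, xdim, probes = 5, eps = 1e-6,
                           seed = 1) {
  set.seed(seed)
  l <- make_layer()
  x <- array(rnorm(prod(xdim)), xdim)
  R <- NULL
  loss <- function() {
    y <- sfcn:::layer_forward(l, x, training = TRUE)
    if (is.null(R)) R <<- array(rnorm(length(y)), dim(y))
    sum(y * R)
  }
  loss()
  sfcn:::layer_forward(l, x, training = TRUE)
  dx <- sfcn:::layer_backward(l, R)
  rels <- c()
  for (pn in sfcn:::layer_param_names(l)) {
    g <- l[[paste0("g", pn)]]
    for (ii in sample(length(g), min(probes, length(g)))) {
      orig <- l[[pn]]
      v <- orig; v[ii] <- v[ii] + eps; l[[pn]] <- v; f1 <- loss()
      v[ii] <- v[ii] - 2 * eps; l[[pn]] <- v; f0 <- loss()
      l[[pn]] <- orig
      num <- (f1 - f0) / (2 * eps)
      rels <- c(rels, abs(num - g[ii]) / max(1e-6, abs(num) + abs(g[ii])))
    }
  }
  for (ii in sample(length(x), probes)) {
    orig <- x
    x[ii] <- x[ii] + eps; f1 <- loss()
    x[ii] <- x[ii] - 2 * eps; f0 <- loss()
    x <- orig
    num <- (f1 - f0) / (2 * eps)
    rels <- c(rels, abs(num - dx[ii]) / max(1e-6, abs(num) + abs(dx[ii])))
  }
  max(rels)
}

test_that("convolution gradients match finite differences", {
  expect_lt(fd_layer_check(function() sfcn:::conv3d_layer(2L, 3L),
                           c(6, 6, 6, 2, 2)), 1e-5)
  # strided, padded, large-kernel variant (the residual-network stem)
  expect_lt(fd_layer_check(function() sfcn:::conv3d_layer(2L, 3L, 7L, 2L, 3L),
                           c(8, 8, 8, 2, 2)), 1e-5)
  # bias-free 1x1x1 projection
  expect_lt(fd_layer_check(function()
    sfcn:::conv3d_layer(3L, 4L, 1L, 2L, 0L, bias = FALSE),
    c(6, 6, 6, 3, 2)), 1e-5)
})

test_that("normalization gradients match finite differences", {
  expect_lt(fd_layer_check(function() sfcn:::norm3d_layer(3L, "batch"),
                           c(4, 4, 4, 3, 2)), 1e-5)
  expect_lt(fd_layer_check(function() sfcn:::norm3d_layer(3L, "instance"),
                           c(4, 4, 4, 3, 2)), 1e-5)
})

test_that("pooling and residual-block gradients match finite differences", {
  expect_lt(fd_layer_check(function() sfcn:::maxpool3d_layer(2L, 2L, 0L),
                           c(6, 6, 6, 2, 2)), 1e-5)
  expect_lt(fd_layer_check(function() sfcn:::maxpool3d_layer(3L, 2L, 1L),
                           c(7, 7, 7, 2, 2)), 1e-5)
  expect_lt(fd_layer_check(function() sfcn:::global_avgpool_layer(),
                           c(4, 4, 4, 3, 2)), 1e-5)
  expect_lt(fd_layer_check(function()
    sfcn:::basic_block3d(2L, 4L, 2L), c(6, 6, 6, 2, 2), seed = 3), 1e-5)
})

test_that("convolution agrees with a direct dense computation", {
  # independent oracle: naive triple-loop convolution in R
  set.seed(40)
  x <- array(rnorm(5 * 6 * 4), c(5, 6, 4, 1, 1))
  w <- array(rnorm(27), c(3, 3, 3, 1, 1))
  b <- 0.3
  y <- sfcn:::.conv3d_fwd(x, w, b, 1L, 1L)
  naive <- array(0, dim(y))
  xp <- array(0, c(7, 8, 6))
  xp[2:6, 2:7, 2:5] <- x[, , , 1, 1]
  for (i in 1:5) for (j in 1:6) for (k in 1:4)
    naive[i, j, k, 1, 1] <-
      sum(xp[i:(i + 2), j:(j + 2), k:(k + 2)] * w[, , , 1, 1]) + b
  expect_equal(y, naive, tolerance = 1e-12)
})

test_that("batch normalization normalizes to zero mean and unit variance", {
  set.seed(41)
  l <- sfcn:::norm3d_layer(2L, "batch")
  x <- array(rnorm(4 * 4 * 4 * 2 * 3, mean = 5, sd = 3), c(4, 4, 4, 2, 3))
  y <- sfcn:::layer_forward(l, x, training = TRUE)
  for (c_ in 1:2) {
    vals <- as.numeric(y[, , , c_, ])
    expect_equal(mean(vals), 0, tolerance = 1e-8)
    expect_equal(mean(vals^2), 1, tolerance = 1e-4)  # biased batch variance
  }
  # inference mode uses running statistics, not batch statistics
  y2 <- sfcn:::layer_forward(l, x, training = FALSE)
  expect_false(isTRUE(all.equal(y, y2)))
})

test_that("softmax columns are numerically stable probabilities", {
  z <- matrix(c(1000, 1001, -1000, 3, 0, -3), 3, 2)
  p <- sfcn:::softmax_cols(z)
  expect_equal(colSums(p), c(1, 1))
  expect_true(all(is.finite(p)))
})
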