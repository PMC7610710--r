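test_that("SFCN parameter count equals the independent analytic tally", {
  net <- build_sfcn(sfcn_spec(), seed = 1)
  expect_identical(count_parameters(net), 2952936L)
  expect_identical(count_parameters(net), as.integer(sfcn_analytic_params()))
  # rounds to 3.0 million
  expect_equal(round(count_parameters(net) / 1e6, 1), 3.0)
})

test_that("3D ResNet-18/50 counts match the analytic tally and printed values", {
  r18 <- build_resnet3d(resnet3d_spec(18), seed = 1)
  r50 <- build_resnet3d(resnet3d_spec(50), seed = 1)
  expect_identical(count_parameters(r18),
                   as.integer(resnet3d_analytic_params(18)))
  expect_identical(count_parameters(r50),
                   as.integer(resnet3d_analytic_params(50)))
  expect_equal(round(count_parameters(r18) / 1e6, 1), 33.2)
  expect_equal(round(count_parameters(r50) / 1e6, 1), 46.2)
  # SFCN is less than one tenth the size of 3D ResNet-18
  expect_lt(2952936 / count_parameters(r18), 1 / 10)
})

test_that("ResNet stem conv has the closed-form weight count", {
  r18 <- build_resnet3d(resnet3d_spec(18), seed = 1)
  stem <- sfcn:::collect_param_layers(r18)[[1]]
  expect_identical(length(stem$W), 21952L)  # 7^3 * 1 * 64, no bias
  expect_null(stem$b)
})

test_that("block-5 feature map is 5x6x5 for a 160x192x160 input", {
  tr <- sfcn_shape_trace(sfcn_spec())
  expect_equal(unname(tr[5, ]), c(5L, 6L, 5L))
  expect_equal(unname(tr[7, ]), c(1L, 1L, 1L))
  # trace for a 32-cube collapses to 1x1x1 at block 5
  tr32 <- sfcn_shape_trace(tiny_sfcn_spec())
  expect_equal(unname(tr32[5, ]), c(1L, 1L, 1L))
})

test_that("shape trace agrees with an actual forward pass", {
  spec <- sfcn_spec(input_shape = c(32L, 64L, 32L),
                    channel_widths = c(2L, 2L, 2L, 2L, 2L, 4L, 5L),
                    n_output = 5L)
  net <- build_sfcn(spec, seed = 1)
  x <- array(rnorm(32 * 64 * 32), c(32, 64, 32, 1, 1))
  # run blocks 1-5 only (layers 1..20) and inspect the spatial dims
  h <- x
  for (l in net$module$layers[1:20]) h <- sfcn:::layer_forward(l, h)
  expect_equal(dim(h)[1:3],
               unname(sfcn_shape_trace(spec)[5, ]))
  expect_equal(dim(h)[1:3], c(1L, 2L, 1L))
})

test_that("output layer has 40 units for both reference bin configurations", {
  for (b in list(age_bins(42, 82, 1), age_bins(14, 94, 2))) {
    expect_identical(b$n_bins, 40L)
    spec <- sfcn_spec(n_output = b$n_bins)
    expect_identical(spec$channel_widths[7], 40L)
  }
})

test_that("softmax outputs are probability vectors for both architectures", {
  net <- build_sfcn(tiny_sfcn_spec(), seed = 2)
  x <- array(rnorm(32^3 * 3), c(32, 32, 32, 1, 3))
  p <- network_forward(net, x)
  expect_equal(dim(p), c(3L, 10L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-5)

  sexnet <- build_sfcn(sfcn_spec(input_shape = c(32, 32, 32),
                                 channel_widths = c(2, 3, 3, 3, 4, 4, 2),
                                 n_output = 2, task = "sex_binary"), seed = 3)
  p2 <- network_forward(sexnet, x)
  expect_equal(rowSums(p2), rep(1, 3), tolerance = 1e-5)

  r18 <- build_resnet3d(resnet3d_spec(18, n_output = 7), seed = 1)
  p3 <- network_forward(r18, array(rnorm(32^3), c(32, 32, 32)))
  expect_equal(sum(p3), 1, tolerance = 1e-5)
  expect_equal(ncol(p3), 7L)
})

test_that("spec invariants are enforced", {
  expect_error(sfcn_spec(channel_widths = c(32, 64, 128, 256, 256, 64)),
               "7 entries")
  expect_error(sfcn_spec(n_output = 39), "must equal n_output")
  expect_error(sfcn_spec(input_shape = c(100, 192, 160)), "divisible")
  expect_error(resnet3d_spec(34), "unsupported depth")
  expect_error(build_resnet3d(34), "unsupported depth")
})

test_that("adaptive pooling accepts non-divisible shapes >= 32 with fixed output length", {
  spec <- sfcn_spec(input_shape = c(34L, 40L, 36L),
                    channel_widths = c(2L, 2L, 2L, 2L, 2L, 4L, 5L),
                    n_output = 5L, adaptive_pool = TRUE)
  net <- build_sfcn(spec, seed = 1)
  for (shape in list(c(34, 40, 36), c(33, 35, 47), c(32, 64, 32))) {
    p <- network_forward(net, array(rnorm(prod(shape)), c(shape, 1, 1)))
    expect_equal(ncol(p), 5L)
    expect_equal(sum(p), 1, tolerance = 1e-5)
  }
  expect_error(sfcn_spec(input_shape = c(31, 40, 36), adaptive_pool = TRUE,
                         channel_widths = c(2, 2, 2, 2, 2, 4, 5),
                         n_output = 5),
               "at least 32")
})

test_that("inference is deterministic: dropout off, norm in inference mode", {
  # 32x64x32 input keeps a 1x2x1 grid at block 6, so training-mode batch
  # statistics stay non-degenerate and dropout has live activations to mask
  net <- build_sfcn(sfcn_spec(input_shape = c(32, 64, 32),
                              channel_widths = c(2, 3, 3, 3, 4, 16, 10),
                              n_output = 10, dropout_rate = 0.5), seed = 4)
  x <- array(rnorm(32 * 64 * 32), c(32, 64, 32, 1, 1))
  p1 <- network_forward(net, x)
  p2 <- network_forward(net, x)
  expect_identical(p1, p2)
  # training mode with dropout is stochastic
  set.seed(1); q1 <- network_forward(net, x, training = TRUE)
  set.seed(2); q2 <- network_forward(net, x, training = TRUE)
  expect_false(identical(q1, q2))
})

test_that("freezing all layers gives zero trainable parameters", {
  net <- build_sfcn(tiny_sfcn_spec(), seed = 1)
  n0 <- count_parameters(net)
  expect_gt(n0, 0)
  set_trainable(net, FALSE)
  expect_identical(count_parameters(net), 0L)
  set_trainable(net, TRUE)
  expect_identical(count_parameters(net), n0)
})

test_that("a single 3x3x3 conv 1->32 with bias has 896 parameters", {
  l <- sfcn:::conv3d_layer(1L, 32L)
  expect_identical(length(l$W) + length(l$b), 896L)
})

test_that("checkpoints are self-describing and round-trip", {
  net <- build_sfcn(tiny_sfcn_spec(), seed = 9)
  x <- array(rnorm(32^3), c(32, 32, 32, 1, 1))
  p0 <- network_forward(net, x)
  path <- file.path(tempdir(), "run_epoch1.ckpt")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_equal(network_forward(net2, x), p0, tolerance = 1e-12)
  expect_identical(net2$spec$channel_widths, net$spec$channel_widths)
  unlink(path)
})
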