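# A tiny 16^3-input network keeps these optimization checks fast: the spec
# machinery is identical to the full model, only widths and input size shrink.
tiny_train_setup <- function(n = 12, seed = 50, noise = 0.02) {
  set.seed(seed)
  cfg <- phantom_config(n_subjects = n, seed = seed, noise_sd = noise)
  coh <- generate_cohort(cfg, split_fractions = NULL)
  list(cohort = coh,
       ds = volume_dataset(coh$volumes, age = coh$participants$age,
                           sex = coh$participants$sex,
                           id = coh$participants$participant_id))
}

tiny_net <- function(seed = 1, n_output = 40, task = "age_bins") {
  build_sfcn(sfcn_spec(input_shape = c(32L, 64L, 32L),
                       channel_widths = c(2L, 2L, 3L, 3L, 4L, 4L, n_output),
                       n_output = n_output, task = task), seed = seed)
}

test_that("the learning-rate schedule is exact step decay", {
  cfg <- train_config(total_epochs = 100, bins = age_bins(42, 82, 1))
  expect_equal(lr_at_epoch(cfg, 1), 0.01)
  expect_equal(lr_at_epoch(cfg, 30), 0.01)
  expect_equal(lr_at_epoch(cfg, 31), 0.003)
  expect_equal(lr_at_epoch(cfg, 96), 0.01 * 0.3^3, tolerance = 1e-12)
  lrs <- vapply(1:90, function(e) lr_at_epoch(cfg, e), numeric(1))
  expect_equal(unique(lrs), c(0.01, 0.003, 0.0009), tolerance = 1e-12)
})

test_that("train_config validates its invariants", {
  b <- age_bins(42, 82, 1)
  expect_error(train_config(10, lr_init = 0), "positive")
  expect_error(train_config(10, lr_factor = 1.2, bins = b), "in \\(0, 1\\)")
  expect_error(train_config(10, batch_size = 0, bins = b), ">= 1")
  expect_error(train_config(10, task = "age_bins"), "requires `bins`")
  # PAC-style two-year bins default their label sigma to the bin width
  cfg <- train_config(10, bins = age_bins(14, 94, 2))
  expect_equal(cfg$label_sigma, 2)
})

test_that("best-epoch selection minimizes val MAE / maximizes accuracy with earliest-tie rule", {
  h <- data.frame(epoch = 1:3, val_mae = c(3.0, 2.5, 2.7))
  expect_equal(select_best_epoch(h), 2)
  h2 <- data.frame(epoch = 1:2, val_mae = c(2.5, 2.5))
  expect_equal(select_best_epoch(h2), 1)
  h3 <- data.frame(epoch = 1:2, val_accuracy = c(0.9, 0.95))
  expect_equal(select_best_epoch(h3), 2)
  expect_error(select_best_epoch(NULL), "empty")
})

test_that("zero learning rate leaves parameters unchanged but records the loss", {
  setup <- tiny_train_setup(n = 6)
  ds <- setup$ds
  net <- tiny_net(seed = 2)
  before <- sfcn:::snapshot_params(net)
  cfg <- train_config(total_epochs = 1, lr_init = 1e-30, momentum = 0,
                      weight_decay = 0, batch_size = 6, seed = 1,
                      bins = age_bins(42, 82, 1),
                      augment = augment_config(enabled = FALSE))
  fit <- sfcn_train(net, ds, ds, cfg)
  after <- sfcn:::snapshot_params(fit$network)
  for (i in seq_along(before))
    for (p in names(before[[i]]))
      expect_equal(after[[i]][[p]], before[[i]][[p]], tolerance = 1e-25)
  expect_true(is.finite(fit$history$train_loss[1]))
})

test_that("training is deterministic given seed and configuration", {
  setup <- tiny_train_setup(n = 8)
  ds <- setup$ds
  run <- function() {
    net <- tiny_net(seed = 3)
    cfg <- train_config(total_epochs = 2, seed = 7, batch_size = 4,
                        bins = age_bins(42, 82, 1))
    sfcn_train(net, ds, ds, cfg)$history
  }
  expect_identical(run(), run())
})

test_that("loss decreases on a repeated batch at a small learning rate", {
  setup <- tiny_train_setup(n = 4, noise = 0)
  ds <- setup$ds
  # dropout off so the single-batch loss sequence is noise-free
  net <- build_sfcn(sfcn_spec(input_shape = c(32L, 64L, 32L),
                              channel_widths = c(2L, 2L, 3L, 3L, 4L, 4L, 40L),
                              n_output = 40L, dropout_rate = 0), seed = 4)
  cfg <- train_config(total_epochs = 8, lr_init = 0.002, momentum = 0,
                      weight_decay = 0, batch_size = 4, seed = 1,
                      bins = age_bins(42, 82, 1),
                      augment = augment_config(enabled = FALSE))
  fit <- sfcn_train(net, ds, ds, cfg)
  losses <- fit$history$train_loss
  # overall descent, allowing small non-monotone wiggles
  expect_lt(losses[length(losses)], losses[1])
  expect_gt(mean(head(losses, 3)), mean(utils::tail(losses, 3)))
})

test_that("epoch-window statistics expose the validation-train gap", {
  h <- data.frame(epoch = 1:10, lr = 0.01, train_loss = 1,
                  train_mae = seq(5, 1.4, length.out = 10),
                  val_mae = seq(5.5, 2.4, length.out = 10))
  s <- epoch_window_stats(h, 6, 10)
  expect_equal(s$train_mean, mean(h$train_mae[6:10]))
  expect_equal(s$gap_mean, mean(h$val_mae[6:10] - h$train_mae[6:10]))
  expect_error(epoch_window_stats(h, 11, 12), "no epochs")
})

test_that("steps-matched epoch counts scale inversely with training-set size", {
  expect_equal(steps_matched_epochs(130, 12949, 2072), 812)
  expect_equal(steps_matched_epochs(10, 100, 1000), 1)
  expect_gte(steps_matched_epochs(1, 10, 1e6), 1)
})

test_that("fitted models expose the standard S3 surface", {
  setup <- tiny_train_setup(n = 10)
  ds <- setup$ds
  net <- tiny_net(seed = 5)
  cfg <- train_config(total_epochs = 2, seed = 2, batch_size = 5,
                      bins = age_bins(42, 82, 1))
  fit <- sfcn_train(net, ds[1:7], ds[8:10], cfg)
  expect_s3_class(fit, "sfcn_fit")
  expect_output(print(fit), "best epoch")
  ages <- predict(fit, ds[1:3])
  expect_length(ages, 3)
  expect_true(all(ages >= 42.5 & ages <= 81.5))
  probs <- predict(fit, ds[1:3], type = "probs")
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-5)
  rec <- predict(fit, ds[1:3], type = "records")
  expect_s3_class(rec, "prediction_records")
  expect_equal(rec$delta, rec$x - rec$y)
  res <- residuals(fit)
  expect_length(res, 3)
  cf <- coef(fit)
  expect_true(length(cf) > 0)
  f <- file.path(tempdir(), "hist.png")
  grDevices::png(f); plot(fit); grDevices::dev.off(); unlink(f)
  sims <- simulate(fit, nsim = 2, seed = 1, newdata = ds[1:3])
  expect_equal(dim(sims), c(3L, 2L))
  expect_true(all(sims >= 42.5 & sims <= 81.5))
})

test_that("checkpoints written during training follow the naming convention", {
  setup <- tiny_train_setup(n = 6)
  ds <- setup$ds
  dir <- file.path(tempdir(), "ckpts")
  on.exit(unlink(dir, recursive = TRUE))
  net <- tiny_net(seed = 6)
  cfg <- train_config(total_epochs = 2, seed = 1, batch_size = 6,
                      bins = age_bins(42, 82, 1), checkpoint_dir = dir,
                      checkpoint_every = 1L, run_name = "tiny")
  sfcn_train(net, ds, ds, cfg)
  expect_true(all(file.exists(file.path(dir, c("tiny_epoch1.ckpt",
                                               "tiny_epoch2.ckpt")))))
})
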