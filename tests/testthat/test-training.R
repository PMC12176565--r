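test_that("a flat validation loss stops training after patience + 1 epochs", {
  cfg <- train_config()
  out <- simulate_schedule(rep(0.7, 40), cfg)
  expect_equal(out$stopped_epoch, cfg$es_patience + 1L)
  expect_equal(out$best_epoch, 1L)
})

test_that("learning rate halves after each plateau and floors at min_lr", {
  cfg <- train_config()
  out <- simulate_schedule(rep(0.7, 13), cfg)
  lr <- out$trace$lr
  # epoch 1 improves over +Inf; decays fire 5 stagnant epochs later
  expect_equal(lr[1:6], rep(0.001, 6))
  expect_equal(lr[7:11], rep(0.0005, 5))
  expect_equal(lr[12:13], c(0.00025, 0.00025))

  long <- simulate_schedule(c(1, rep(0.9, 100)), train_config(max_epochs = 200,
                                                              es_patience = 200))
  expect_true(all(long$trace$lr >= 1e-7))
  expect_equal(min(long$trace$lr), 1e-7)
})

test_that("improvement must beat the strict tolerance", {
  cfg <- train_config()
  # decreasing by < 1e-9 per epoch is stagnation
  losses <- 0.5 - (seq_len(30)) * 1e-12
  out <- simulate_schedule(losses, cfg)
  expect_equal(out$stopped_epoch, cfg$es_patience + 1L)
  # a real improvement resets both patience counters
  # last real improvement at epoch 13 (0.4 then 0.39); stop 15 epochs later
  out2 <- simulate_schedule(c(0.5, rep(0.49, 10), 0.4, rep(0.39, 20)), cfg)
  expect_equal(out2$stopped_epoch, 13L + cfg$es_patience)
  expect_equal(out2$best_epoch, 13L)
})

test_that("stratified folds partition samples and respect the seed", {
  labels <- rep(c(0, 1), c(90, 10))
  f1 <- make_folds(labels, k = 10, seed = 5)
  f2 <- make_folds(labels, k = 10, seed = 5)
  f3 <- make_folds(labels, k = 10, seed = 6)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_equal(sort(unique(f1)), 1:10)
  expect_true(all(tabulate(f1, 10) == 10))
  for (k in 1:10) {
    expect_equal(sum(labels[f1 == k] == 1), 1)  # within +-1 of 10% of 10
  }
})

test_that("grouped folds never split a recording", {
  labels <- rep(c(0, 0, 1), 20)
  groups <- rep(sprintf("rec%02d", 1:20), each = 3)
  glabel <- rep(c(0, 1), 10)
  labels <- glabel[rep(1:20, each = 3)]
  f <- make_folds(labels, groups = groups, k = 5, seed = 1)
  per_group_folds <- tapply(f, groups, function(v) length(unique(v)))
  expect_true(all(per_group_folds == 1))
  expect_error(make_folds(labels, groups = groups, k = 11),
               "fewer than")
  expect_error(make_folds(c(0, 1), groups = c("a", "a")),
               "multiple labels")
})

test_that("training rejects an empty training set", {
  m <- build_model(model_from_id(1, input_shape = c(8L, 8L)), seed = 1)
  empty <- list(x = list(), y = integer())
  val <- list(x = list(matrix(0, 8, 8)), y = 0L)
  expect_error(train(m, empty, val), "empty training set")
})

test_that("cross-validation evaluates each requested fold exactly once", {
  set.seed(41)
  n_rec <- 8
  xs <- list(); ys <- integer(); recs <- character()
  for (r in seq_len(n_rec)) {
    lab <- (r - 1) %% 2
    for (s in 1:2) {
      xs <- c(xs, list(matrix(rnorm(64, mean = lab), 8, 8)))
      ys <- c(ys, lab)
      recs <- c(recs, sprintf("rec%d", r))
    }
  }
  ds <- list(x = xs, y = ys, recording = recs)
  cv <- crossvalidate(ds, model_id = 1, cfg = train_config(max_epochs = 1,
                                                           seed = 2),
                      k = 4, folds_to_run = 1:2)
  expect_length(cv$reports, 2)
  expect_equal(sort(unique(cv$folds)), 1:4)
  # grouped: both segments of a recording share a fold
  expect_true(all(tapply(cv$folds, recs, function(v) length(unique(v))) == 1))
  expect_equal(cv$summary$stat, c("fold", "fold", "mean", "sd"))
  expect_true(all(is.finite(cv$summary$accuracy)))
})

test_that("the training loop reproduces exactly under a fixed seed", {
  set.seed(40)
  xs <- lapply(1:12, function(i) matrix(rnorm(64), 8, 8))
  ys <- rep(0:1, 6)
  data <- list(x = xs, y = ys)
  cfg <- model_config(input_shape = c(8L, 8L), filters = c(2, 2, 2, 2, 2, 2),
                      cbam_mask = c(TRUE, rep(FALSE, 5)), cbam_r = 2,
                      cbam_k = 3, fc_units = 4)
  tc <- train_config(max_epochs = 2, seed = 7)
  fit1 <- train(build_model(cfg, seed = 7), data, data, tc)
  fit2 <- train(build_model(cfg, seed = 7), data, data, tc)
  expect_identical(fit1$history, fit2$history)
  expect_true(all(diff(fit1$history$lr) <= 0))
})
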