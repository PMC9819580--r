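test_that("patch extraction is seeded, paired and correctly counted", {
  pairs <- tiny_pairs(n = 3, shape = c(64, 48), seed = 51)
  ps1 <- extract_patches(pairs, per_image = 10, size = 32, seed = 5)
  ps2 <- extract_patches(pairs, per_image = 10, size = 32, seed = 5)
  expect_identical(ps1$inputs, ps2$inputs)
  expect_identical(dim(ps1$inputs)[4], 30L)
  expect_identical(ps1$source_indices, rep(1:3, each = 10))

  ## pairing: extracting from identical input/target stacks gives identical
  ## patches (coordinates are shared)
  same <- pairs; same$input <- same$target
  ps3 <- extract_patches(same, per_image = 6, size = 32, seed = 8)
  expect_identical(ps3$inputs, ps3$targets)
})

test_that("an image exactly the patch size yields identical corner patches", {
  set.seed(53)
  a <- array(runif(32 * 32), c(32, 32, 1))
  pairs <- structure(list(input = a, target = a, fraction = 0.2,
                          dynamic_range_db = 60), class = "paired_dataset")
  ps <- extract_patches(pairs, per_image = 64, size = 32, seed = 1)
  expect_identical(dim(ps$inputs)[4], 64L)
  for (j in sample(2:64, 5))
    expect_identical(ps$inputs[, , 1, j], ps$inputs[, , 1, 1])
})

test_that("undersized images are rejected by name", {
  pairs <- tiny_pairs(n = 1, shape = c(48, 48), seed = 54)
  expect_error(extract_patches(pairs, size = 128, seed = 1), "smaller")
})

test_that("training defaults mirror the printed protocol", {
  cfg <- train_config()
  expect_identical(cfg$batch_size, 16L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$beta1, 0.9)
  expect_equal(cfg$beta2, 0.999)
  expect_identical(cfg$max_epochs, 300L)
})

test_that("single-batch overfit: loss halves within 50 steps", {
  pairs <- tiny_pairs(n = 1, shape = c(48, 48), seed = 55)
  ps <- extract_patches(pairs, per_image = 16, size = 16, seed = 2)
  m <- build_model("srcnn_classic", 16, seed = 3)
  cfg <- train_config(max_epochs = 50, early_stop_patience = 0,
                      learning_rate = 1e-3, seed = 4)
  m2 <- train_model(m, ps, config = cfg)
  h <- m2$history
  expect_lt(h$train_loss[nrow(h)], 0.5 * h$train_loss[1])
})

test_that("history has exactly one row per epoch when early stop disabled", {
  pairs <- tiny_pairs(n = 1, shape = c(48, 48), seed = 56)
  ps <- extract_patches(pairs, per_image = 8, size = 16, seed = 2)
  m <- build_model("srcnn_classic", 16, seed = 3)
  m1 <- train_model(m, ps, config = train_config(max_epochs = 1,
                                                 early_stop_patience = 0))
  expect_identical(nrow(m1$history), 1L)
})

test_that("training is resumable through save/load", {
  pairs <- tiny_pairs(n = 1, shape = c(48, 48), seed = 57)
  ps <- extract_patches(pairs, per_image = 8, size = 16, seed = 2)
  cfg1 <- train_config(max_epochs = 2, early_stop_patience = 0, seed = 6)
  mA <- train_model(build_model("srcnn_classic", 16, seed = 9), ps, config = cfg1)
  ## train 1, save, load, train 1 more: same history length
  cfg_half <- train_config(max_epochs = 1, early_stop_patience = 0, seed = 6)
  mB <- train_model(build_model("srcnn_classic", 16, seed = 9), ps, config = cfg_half)
  f <- tempfile(fileext = ".rds")
  save_model(mB, f)
  mB2 <- load_model(f)
  expect_identical(mB$params, mB2$params)
  mB3 <- train_model(mB2, ps, config = cfg_half)
  expect_identical(nrow(mB$history) + nrow(mB3$history), nrow(mA$history))
})

test_that("early stopping halts after `patience` non-improving epochs", {
  pairs <- tiny_pairs(n = 1, shape = c(48, 48), seed = 58)
  ps <- extract_patches(pairs, per_image = 8, size = 16, seed = 2)
  ## learning rate 0: validation loss can never improve after epoch 1
  cfg <- train_config(max_epochs = 50, early_stop_patience = 3,
                      learning_rate = 0, seed = 7)
  m <- train_model(build_model("srcnn_classic", 16, seed = 9), ps,
                   val_patches = ps, config = cfg)
  expect_lte(nrow(m$history), 5)
})

test_that("NaN losses abort with a diagnostic", {
  pairs <- tiny_pairs(n = 1, shape = c(48, 48), seed = 59)
  ps <- extract_patches(pairs, per_image = 8, size = 16, seed = 2)
  cfg <- train_config(max_epochs = 4, early_stop_patience = 0,
                      learning_rate = 1e150, seed = 8,
                      loss = loss_config("pl1", tau = 1e10))
  expect_error(train_model(build_model("srcnn_classic", 16, seed = 9), ps,
                           config = cfg),
               "loss")
})
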