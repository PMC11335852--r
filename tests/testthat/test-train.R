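# Training loop: least-squares recovery, early stopping, determinism,
# frozen inputs, checkpointing.

test_that("word-level training recovers the closed-form least squares map", {
  world <- make_world(V = 200, d = 8, c = 4, D_img = 4, seed = 31)
  ds <- make_caption_dataset(world, n_samples = 800, len_range = c(1, 1),
                             noise_sd = 0)
  cfg <- grounding_config(d = 8, c = 4, D_img = 4,
                          encoder_kind = "word_level", max_epochs = 300,
                          patience = 40, batch_size = 256,
                          learning_rate = 0.01, seed = 5)
  fit <- train_grounding(ds, world$table, NULL, cfg)
  # oracle: normal equations on the planted single-token construction,
  # whose unique solution is M* itself (full-rank noiseless design)
  relF <- norm(fit$model$params$M - world$M_star, "F") /
    norm(world$M_star, "F")
  expect_lt(relF, 1e-3)
})

test_that("word-level training PCA-reduces mismatched image dimensions", {
  world <- make_world(V = 80, d = 6, c = 3, D_img = 10, seed = 32)
  ds <- make_caption_dataset(world, n_samples = 300, len_range = c(2, 4),
                             noise_sd = 0.01)
  cfg <- grounding_config(d = 6, c = 3, D_img = 10,
                          encoder_kind = "word_level", max_epochs = 30,
                          patience = 5, batch_size = 128, seed = 5)
  fit <- train_grounding(ds, world$table, NULL, cfg)
  expect_false(is.null(fit$model$pca))
  expect_equal(dim(fit$model$pca$rotation), c(10L, 3L))
  # too few samples for the requested PCA dimension errors out
  tiny <- make_caption_dataset(world, n_samples = 2, len_range = c(2, 2),
                               noise_sd = 0, val_fraction = 0)
  expect_error(train_grounding(tiny, world$table, NULL, cfg))
})

test_that("early stopping halts within patience and restores best weights", {
  world <- make_world(V = 60, d = 6, c = 4, D_img = 8, seed = 33)
  ds <- make_caption_dataset(world, n_samples = 300, len_range = c(2, 5),
                             noise_sd = 0.3)
  cfg <- grounding_config(d = 6, c = 4, D_img = 8, encoder_kind = "bow",
                          encoder_units = 8, max_epochs = 40, patience = 3,
                          batch_size = 64, learning_rate = 0.01, seed = 6)
  fit <- train_grounding(ds, world$table, NULL, cfg)
  best <- attr(fit$trace, "best_epoch")
  stopped <- attr(fit$trace, "stopped_epoch")
  expect_lte(stopped, cfg$max_epochs)
  expect_lte(stopped - best, cfg$patience)
  # returned parameters are the best-epoch ones: their validation loss
  # equals the trace minimum
  val <- grounding_loss(fit$model, ds, world$table, "validation")
  expect_equal(val, min(fit$trace$val_loss), tolerance = 1e-10)
})

test_that("identical seeds give identical models and traces", {
  world <- make_world(V = 50, d = 5, c = 3, D_img = 6, seed = 34)
  ds <- make_caption_dataset(world, n_samples = 150, len_range = c(2, 4),
                             noise_sd = 0.1)
  cfg <- grounding_config(d = 5, c = 3, D_img = 6, encoder_kind = "lstm",
                          encoder_units = 6, max_epochs = 5, patience = 5,
                          batch_size = 32, seed = 12)
  f1 <- train_grounding(ds, world$table, NULL, cfg)
  f2 <- train_grounding(ds, world$table, NULL, cfg)
  expect_identical(f1$model$params$M, f2$model$params$M)
  expect_identical(f1$trace$train_loss, f2$trace$train_loss)
  expect_identical(f1$trace$val_loss, f2$trace$val_loss)
  # a different seed moves the solution
  cfg2 <- grounding_config(d = 5, c = 3, D_img = 6, encoder_kind = "lstm",
                           encoder_units = 6, max_epochs = 5, patience = 5,
                           batch_size = 32, seed = 13)
  f3 <- train_grounding(ds, world$table, NULL, cfg2)
  expect_gt(norm(f3$model$params$M - f1$model$params$M, "F"), 0)
})

test_that("the textual embedding table is frozen through training", {
  world <- make_world(V = 40, d = 5, c = 3, D_img = 6, seed = 35)
  before <- serialize(world$table, NULL)
  ds <- make_caption_dataset(world, n_samples = 100, len_range = c(2, 3),
                             noise_sd = 0.1)
  cfg <- grounding_config(d = 5, c = 3, D_img = 6, encoder_kind = "bow",
                          encoder_units = 6, max_epochs = 3, patience = 3,
                          batch_size = 32, seed = 3)
  invisible(train_grounding(ds, world$table, NULL, cfg))
  expect_identical(serialize(world$table, NULL), before)
})

test_that("lstm training beats the constant mean-image predictor", {
  world <- make_world(V = 80, d = 8, c = 4, D_img = 8, seed = 36)
  ds <- make_caption_dataset(world, n_samples = 600, len_range = c(2, 5),
                             noise_sd = 0.05)
  cfg <- grounding_config(d = 8, c = 4, D_img = 8, encoder_kind = "lstm",
                          encoder_units = 8, max_epochs = 25, patience = 25,
                          batch_size = 64, seed = 21)
  fit <- train_grounding(ds, world$table, NULL, cfg)
  val <- grounding_loss(fit$model, ds, world$table, "validation")
  # baseline oracle computed on the validation split itself
  val_imgs <- ds$images[ds$split == "validation", , drop = FALSE]
  base <- mean(sweep(val_imgs, 2, colMeans(val_imgs))^2)
  expect_lt(val, base)
})

test_that("empty or uncovered training data is rejected", {
  world <- make_world(V = 30, d = 4, c = 2, D_img = 4, seed = 37)
  ds <- make_caption_dataset(world, n_samples = 50, len_range = c(2, 3),
                             noise_sd = 0)
  cfg <- grounding_config(d = 4, c = 2, D_img = 4, encoder_kind = "bow",
                          encoder_units = 4, max_epochs = 2, seed = 1)
  other_table <- tiny_table(V = 5, d = 4, seed = 99)
  expect_error(
    suppressMessages(train_grounding(ds, other_table, NULL, cfg)),
    "no vocabulary")
  ds_empty <- ds
  ds_empty$split <- rep("validation", length(ds$split))
  expect_error(train_grounding(ds_empty, world$table, NULL, cfg),
               "training split")
})

test_that("checkpoints round-trip the model through JSON", {
  world <- make_world(V = 40, d = 5, c = 3, D_img = 6, seed = 38)
  ds <- make_caption_dataset(world, n_samples = 120, len_range = c(2, 4),
                             noise_sd = 0.1)
  cfg <- grounding_config(d = 5, c = 3, D_img = 6, encoder_kind = "gru",
                          encoder_units = 6, max_epochs = 3, patience = 3,
                          batch_size = 32, seed = 2)
  fit <- train_grounding(ds, world$table, NULL, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit$model, f)
  back <- load_checkpoint(f)
  expect_equal(back$config$encoder_kind, "gru")
  expect_equal(back$params$M, fit$model$params$M, tolerance = 1e-12)
  expect_equal(back$vocabulary, fit$model$vocabulary)
  # grounding through the reloaded model agrees with the original
  expect_equal(ground_vocabulary(back, world$table)$vectors,
               ground_vocabulary(fit$model, world$table)$vectors,
               tolerance = 1e-10)
  expect_error(load_checkpoint(file.path(tempdir(), "nope.json")),
               "no such file")
})
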