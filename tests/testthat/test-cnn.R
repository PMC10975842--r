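test_that("the default architecture has the designed parameter budget", {
  arch <- cnn_architecture()
  p <- count_params(arch)
  expect_identical(p$per_layer, c(5304L, 11544L, 5784L, 968L))
  expect_identical(p$total, 23600L)
  expect_identical(downsample_factor(arch), 44L)
})

test_that("forward pass maps (110000, 1) audio to (2500, 8) ECG", {
  model <- build_model(seed = 42)
  out <- predict_ecg(model, audio_stream(numeric(110000), 11000))
  expect_identical(dim(out$samples), c(2500L, 8L))
  expect_equal(out$fs, 250)
  expect_identical(colnames(out$samples),
                   c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"))
})

test_that("short audio is zero-padded with a warning; wrong rate rejected", {
  model <- build_model(seed = 42)
  expect_warning(out <- predict_ecg(model, audio_stream(numeric(100001), 11000)),
                 "zero-padded")
  expect_identical(nrow(out$samples), as.integer(ceiling(100001 / 44)))
  expect_error(predict_ecg(model, audio_stream(numeric(110000), 8000)),
               "expects")
})

test_that("pool windows that do not divide the input length are an error", {
  # predict_ecg pads to a multiple of the pool product, so the guard sits
  # in the compiled forward pass
  model <- build_model(tiny_cnn_arch(), seed = 1)
  expect_error(
    cnn_predict_cpp(model$weights, ecgsonify:::arch_for_cpp(model$arch),
                    matrix(numeric(101), ncol = 1)),
    "divisible")
})

test_that("the untrained network is positively homogeneous", {
  # linear activations and zero initial biases; max pooling commutes with
  # positive scaling, so predict(a*x) = a*predict(x) for a > 0
  model <- build_model(seed = 42)
  set.seed(43)
  x <- runif(44 * 500, -1, 1)
  base <- cnn_predict_cpp(model$weights, ecgsonify:::arch_for_cpp(model$arch),
                          matrix(x, ncol = 1))
  for (a in c(0.5, 3)) {
    scaled <- cnn_predict_cpp(model$weights,
                              ecgsonify:::arch_for_cpp(model$arch),
                              matrix(a * x, ncol = 1))
    expect_equal(scaled, a * base, tolerance = 1e-5)
  }
})

test_that("training is deterministic under a fixed seed", {
  pairs <- tiny_pairs(n = 8)
  tc <- train_config(batch_size = 4L, max_epochs = 2L,
                     early_stop_patience = 2L, seed = 9L)
  m1 <- train_cnn(build_model(seed = 1), pairs, tc)
  m2 <- train_cnn(build_model(seed = 1), pairs, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
})

test_that("zero learning rate trips the early stop at patience + 1 epochs", {
  pairs <- tiny_pairs(n = 6)
  tc <- train_config(learning_rate = 0, batch_size = 4L, max_epochs = 50L,
                     early_stop_patience = 3L, seed = 9L)
  m <- train_cnn(build_model(seed = 1), pairs, tc)
  expect_identical(m$epochs_run, 4L)
  expect_identical(m$best_epoch, 1L)
  expect_equal(sd(m$history$val_rmse_mv), 0)
})

test_that("training reduces the loss on a small dataset", {
  pairs <- tiny_pairs(n = 8)
  tc <- train_config(batch_size = 4L, max_epochs = 15L,
                     early_stop_patience = 15L, val_fraction = 0, seed = 10L)
  m <- train_cnn(build_model(seed = 2), pairs, tc)
  expect_lt(tail(m$history$train_rmse_mv, 1),
            0.5 * m$history$train_rmse_mv[1])
})

test_that("malformed datasets are rejected with informative errors", {
  model <- build_model(seed = 1)
  expect_error(train_cnn(model, list()), "empty")
  bad <- list(list(audio = numeric(100), ecg = matrix(0, 10, 8)))
  expect_error(train_cnn(model, bad), "44 times")
  bad2 <- list(list(audio = numeric(440), ecg = matrix(0, 10, 5)))
  expect_error(train_cnn(model, bad2), "leads")
})

test_that("checkpoints are self-describing and bit-exact", {
  model <- build_model(seed = 42)
  set.seed(44)
  x <- audio_stream(runif(110000, -1, 1), 11000)
  ref <- predict_ecg(model, x)
  path <- file.path(tempdir(), "model.json")
  save_cnn(model, path)
  # no architecture argument: the checkpoint carries it
  back <- load_cnn(path)
  expect_identical(back$arch$conv_kernels, model$arch$conv_kernels)
  expect_identical(predict_ecg(back, x)$samples, ref$samples)
  # truncated checkpoints must not load
  txt <- readLines(path, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 300), path)
  expect_error(load_cnn(path), "corrupt")
  unlink(path)
})
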