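test_that("autoencoder shapes honour the contract at multiple input sizes", {
  for (s in c(64L, 224L)) {
    ae <- build_autoencoder(s, c(4L, 4L, 8L, 8L, 8L), seed = 1)
    latent <- ae$encoder$shapes[[length(ae$encoder$layers)]]
    expect_lt(latent[1], s)
    expect_identical(latent[1:2], c(s %/% 8L, s %/% 8L))
    x <- array(runif(s * s), dim = c(s, s, 1, 1))
    k <- reconstruct(ae, x)
    expect_identical(dim(k), c(s, s, 1L, 1L))
    expect_true(all(k > 0 & k < 1)) # sigmoid range
  }
  expect_error(build_autoencoder(50), "multiple of 8")
})

test_that("extracted encoder reproduces latents and is an independent copy", {
  ae <- build_autoencoder(32, c(4L, 4L, 8L, 8L, 8L), seed = 2)
  enc <- extract_encoder(ae)
  x <- array(runif(32 * 32 * 2), dim = c(32, 32, 1, 2))
  expect_identical(encode(enc, x),
                   asNamespace("randnet")$forward_network(ae$encoder, x))
  enc2 <- extract_encoder(ae)
  expect_identical(enc$net$weights, enc2$net$weights)

  mutated <- enc
  mutated$net$weights[[1]]$W[] <- 0
  expect_false(identical(ae$encoder$weights[[1]]$W,
                         mutated$net$weights[[1]]$W))
  expect_identical(encode(enc, x),
                   asNamespace("randnet")$forward_network(ae$encoder, x))
})

test_that("subnetworks emit simplex rows and share encoder weights at birth", {
  ae <- build_autoencoder(32, c(4L, 4L, 8L, 8L, 8L), seed = 3)
  enc <- extract_encoder(ae)
  sn1 <- build_subnetwork(enc, seed = 10)
  sn2 <- build_subnetwork(enc, seed = 11)
  expect_identical(sn1$encoder$weights, sn2$encoder$weights)

  x <- array(runif(32 * 32 * 7), dim = c(32, 32, 1, 7))
  p <- predict(sn1, x)
  expect_identical(dim(p), c(7L, 6L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))

  two <- build_subnetwork(enc, num_classes = 2L, seed = 12)
  expect_identical(ncol(predict(two, x)), 2L)
})

test_that("autoencoder training reduces reconstruction loss deterministically", {
  imgs <- lapply(1:40, function(i)
    generate_class_image(i %% 6, 32, noise_sd = 0.02, seed = 400 + i))
  pool <- unlabeled_dataset(imgs)
  ae <- build_autoencoder(32, c(4L, 8L, 8L, 8L, 8L), seed = 5)

  ae0 <- train_autoencoder(ae, pool, epochs = 0L)
  expect_identical(ae0$encoder$weights, ae$encoder$weights)
  expect_length(ae0$training_log, 0L)

  tr1 <- train_autoencoder(ae, pool, epochs = 3L, batch_size = 8L, seed = 6)
  expect_length(tr1$training_log, 3L)
  expect_lt(tr1$training_log[3], tr1$training_log[1])

  tr2 <- train_autoencoder(ae, pool, epochs = 3L, batch_size = 8L, seed = 6)
  expect_identical(tr1$encoder$weights, tr2$encoder$weights)
  expect_identical(tr1$decoder$weights, tr2$decoder$weights)

  expect_error(train_autoencoder(ae, unlabeled_dataset(list()), epochs = 1L),
               "empty unlabeled pool")
})

test_that("fine-tuning learns separable data and diversifies the encoder", {
  ds <- generate_dataset(synthetic_config(
    image_size = 32, counts_per_class = rep(10L, 6), unlabeled_count = 60L,
    noise_sd = 0.02, seed = 55))
  ae <- build_autoencoder(32, c(4L, 8L, 16L, 16L, 16L), seed = 7)
  ae <- train_autoencoder(ae, ds$unlabeled, epochs = 2L, batch_size = 16L,
                          seed = 7)
  enc <- extract_encoder(ae)

  sn <- build_subnetwork(enc, pool = "flatten", seed = 8)
  frozen <- fine_tune_subnetwork(sn, ds$labeled, ds$labeled$labels,
                                 epochs = 0L)
  expect_identical(frozen$encoder$weights, sn$encoder$weights)

  tuned <- fine_tune_subnetwork(sn, ds$labeled, ds$labeled$labels,
                                epochs = 25L, batch_size = 20L,
                                patience = 50L, seed = 8)
  p <- predict(tuned, ds$labeled)
  acc <- mean(max.col(p, ties.method = "first") - 1L == ds$labeled$labels)
  expect_gte(acc, 0.9)
  expect_false(identical(tuned$encoder$weights, sn$encoder$weights))

  # different bootstrap subsets give different fine-tuned encoders
  other_idx <- c(seq(1, 60, by = 2))
  other <- fine_tune_subnetwork(
    build_subnetwork(enc, pool = "flatten", seed = 8),
    ds$labeled$images[other_idx], ds$labeled$labels[other_idx],
    epochs = 2L, batch_size = 20L, patience = 50L, seed = 9)
  tuned2 <- fine_tune_subnetwork(
    build_subnetwork(enc, pool = "flatten", seed = 8),
    ds$labeled, ds$labeled$labels,
    epochs = 2L, batch_size = 20L, patience = 50L, seed = 9)
  expect_false(identical(other$encoder$weights, tuned2$encoder$weights))
})

test_that("the stacking head has the right geometry", {
  expect_identical(build_stacking_network(33)$input_dim, 198L)
  expect_identical(build_stacking_network(1)$input_dim, 6L)
  expect_error(build_stacking_network(0), "config error")

  st <- build_stacking_network(3, seed = 13)
  feats <- matrix(runif(5 * 18), 5, 18)
  p <- predict(st, feats)
  expect_identical(dim(p), c(5L, 6L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_error(predict(st, feats[, 1:12]), "shape error")
})
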