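test_that("the trained ensemble has the promised structure and provenance", {
  model <- tiny_ensemble()
  expect_s3_class(model, "randnet_ensemble")
  expect_length(model$subnetworks, 3L)
  expect_identical(model$stacker$input_dim, 18L)
  expect_identical(model$n, 3L)

  # stage order of the training recipe
  expect_identical(model$provenance$stages,
                   c("inputs", "normalize", "train_autoencoder",
                     "extract_encoder", "stratified_bootstrap",
                     "fine_tune_subnetworks", "connect_stacking",
                     "train_stacking", "final_model"))
  expect_identical(model$provenance$stage_seeds$subnetworks, 5L + 1L + 1:3)
  expect_identical(model$provenance$stage_seeds$stacker, 1005L)

  pools <- tiny_pools()
  pred <- predict(model, pools$labeled)
  expect_identical(dim(pred$prob),
                   c(length(pools$labeled$images), 6L))
  expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-6))
  expect_true(all(pred$class %in% 0:5))
})

test_that("identical seeds reproduce identical predictions", {
  pools <- tiny_pools()
  m1 <- train_randnet(pools$unlabeled, pools$labeled, n = 2L,
                      config = tiny_config(), seed = 21L)
  m2 <- train_randnet(pools$unlabeled, pools$labeled, n = 2L,
                      config = tiny_config(), seed = 21L)
  probe <- pools$labeled$images[seq(1, 72, by = 9)]
  expect_identical(predict(m1, probe)$prob, predict(m2, probe)$prob)
})

test_that("a uniform stacker output breaks ties toward class 0", {
  model <- tiny_ensemble()
  # zero weights in the stacking head force a uniform softmax output
  for (i in seq_along(model$stacker$net$weights))
    if (!is.null(model$stacker$net$weights[[i]])) {
      model$stacker$net$weights[[i]]$W[] <- 0
      model$stacker$net$weights[[i]]$b[] <- 0
    }
  pools <- tiny_pools()
  pred <- predict(model, pools$labeled$images[1:4])
  expect_true(all(abs(pred$prob - 1 / 6) < 1e-12))
  expect_identical(pred$class, rep(0L, 4L))
})

test_that("subnetwork-count selection returns a coherent grid summary", {
  pools <- tiny_pools()
  sel <- select_num_subnetworks(pools$unlabeled, pools$labeled,
                                grid = c(2L, 1L), k = 2L,
                                config = tiny_config(), seed = 31L)
  expect_identical(sel$grid, c(1L, 2L))
  expect_length(sel$mean_val_accuracy, 2L)
  expect_true(all(sel$mean_val_accuracy >= 0 & sel$mean_val_accuracy <= 1))
  expect_true(all(sel$mean_val_loss >= 0))
  expect_true(sel$best_n %in% sel$grid)

  single <- select_num_subnetworks(pools$unlabeled, pools$labeled,
                                   grid = 3L, k = 2L,
                                   config = tiny_config(), seed = 32L)
  expect_identical(single$best_n, 3L)
})

test_that("holdout evaluation conserves counts and never leaks", {
  pools <- tiny_pools()
  fit <- final_fit_and_holdout(pools$labeled, pools$unlabeled,
                               config = tiny_config(), seed = 41L)
  expect_identical(sum(fit$confusion), length(fit$split$test_indices))
  expect_length(intersect(fit$split$train_indices, fit$split$test_indices), 0L)
  expect_identical(fit$metrics$n_evaluated, sum(fit$confusion))
  # per-class column totals match the split plan
  expect_identical(as.integer(colSums(fit$confusion)),
                   fit$split$per_class_test_counts)
})
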