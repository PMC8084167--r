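#' Train a RandNet ensemble
#'
#' Executes the full training recipe in order: (1) take the two pools,
#' (2) normalize and resize to the network input scale, (3) pretrain the
#' autoencoder on the unlabeled pool, (4) extract its encoder, (5) draw `n`
#' stratified bootstrap subsets of the labeled training pool, (6) fine-tune
#' one subnetwork per subset (out-of-bag samples drive early stopping),
#' (7) connect the subnetwork outputs to a stacking head, (8) train the
#' stacking head on all training data (subnetworks frozen by default; set
#' `joint_finetune = TRUE` in the config for an additional joint pass), and
#' (9) return the final model.  The executed stage order is recorded in
#' `provenance$stages`.
#'
#' Seeding is derived from the single `seed`: the autoencoder uses `seed`,
#' subnetwork `i` uses `seed + 1 + i`, the stacking head `seed + 1000` and
#' the bootstrap draw `seed + 2000`, so every run is replayable.
#'
#' @param unlabeled Unlabeled pool (`unlabeled_dataset`, image list, or
#'   normalized array).
#' @param labeled_train Labeled training pool ([labeled_dataset]).
#' @param n Number of subnetworks (default `config$n_subnetworks`).
#' @param config A [randnet_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return A `randnet_ensemble`: `subnetworks` (list of n), `stacker`, `n`,
#'   `input_size`, `num_classes`, and `provenance` (stages, seeds, config
#'   hash, bootstrap plan).
#' @export
train_randnet <- function(unlabeled, labeled_train, n = NULL,
                          config = randnet_config(), seed = NULL) {
  if (is.null(n)) n <- config$n_subnetworks
  if (is.null(seed)) seed <- config$seed
  if (!is_count(n, 1L)) stopf("n must be a positive integer")
  if (!inherits(labeled_train, "labeled_dataset"))
    stopf("labeled_train must be a labeled_dataset")
  if (length(labeled_train$images) == 0L)
    stopf("data error: empty labeled pool")
  n_class <- length(labeled_train$class_names)
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  note("normalize")
  xu <- as_input_array(unlabeled, config$input_size)
  if (dim(xu)[4] == 0L) stopf("data error: empty unlabeled pool")
  xl <- as_input_array(labeled_train, config$input_size)
  labels <- labeled_train$labels

  note("train_autoencoder")
  ae <- build_autoencoder(config$input_size, config$filters, config$kernel,
                          seed = stage_seed(seed, "autoencoder"))
  ae <- train_autoencoder(ae, xu, epochs = config$ae_epochs,
                          batch_size = config$ae_batch,
                          seed = stage_seed(seed, "autoencoder"))

  note("extract_encoder")
  encoder <- extract_encoder(ae)

  note("stratified_bootstrap")
  boot <- stratified_bootstrap(labels, n, stage_seed(seed, "splits"),
                               n_class = n_class)

  note("fine_tune_subnetworks")
  subnets <- vector("list", n)
  for (i in seq_len(n)) {
    si <- stage_seed(seed, "subnetwork", i)
    subnet <- build_subnetwork(encoder, num_classes = n_class,
                               hidden = config$topper_hidden,
                               pool = config$topper_pool, seed = si)
    idx <- boot$subsets[[i]]
    oob <- setdiff(seq_along(labels), unique(idx))
    validation <- if (length(oob))
      list(images = xl[, , , oob, drop = FALSE], labels = labels[oob])
    subnets[[i]] <- fine_tune_subnetwork(
      subnet, xl[, , , idx, drop = FALSE], labels[idx],
      epochs = config$subnet_epochs, batch_size = config$subnet_batch,
      lr = config$learning_rate, patience = config$patience,
      validation = validation, seed = si)
  }

  note("connect_stacking")
  features <- do.call(cbind, lapply(subnets, predict, xl))
  stacker <- build_stacking_network(n, num_classes = n_class,
                                    hidden = config$stacker_hidden,
                                    seed = stage_seed(seed, "stacker"))

  note("train_stacking")
  stacker <- train_stacking(stacker, features, labels,
                            epochs = config$stacker_epochs,
                            batch_size = config$subnet_batch,
                            lr = config$learning_rate,
                            seed = stage_seed(seed, "stacker"))

  model <- structure(
    list(subnetworks = subnets, stacker = stacker, n = as.integer(n),
         input_size = config$input_size, num_classes = n_class,
         class_names = labeled_train$class_names,
         provenance = list(stages = NULL, seed = as.integer(seed),
                           stage_seeds = list(
                             autoencoder = stage_seed(seed, "autoencoder"),
                             subnetworks = vapply(seq_len(n), function(i)
                               stage_seed(seed, "subnetwork", i), integer(1)),
                             stacker = stage_seed(seed, "stacker"),
                             splits = stage_seed(seed, "splits")),
                           config_hash = config_hash(config),
                           bootstrap = boot,
                           ae_training_log = ae$training_log)),
    class = "randnet_ensemble")

  if (isTRUE(config$joint_finetune) && config$joint_epochs > 0L) {
    note("joint_finetune")
    model <- joint_finetune(model, xl, labels, epochs = config$joint_epochs,
                            batch_size = config$subnet_batch,
                            lr = config$learning_rate,
                            seed = stage_seed(seed, "stacker"))
  }

  note("final_model")
  model$provenance$stages <- c("inputs", stages)
  model
}

# Optional joint pass: backpropagate the stacking loss through the stacking
# head into every subnetwork (softmax Jacobian at each subnetwork output).
joint_finetune <- function(model, x, labels, epochs, batch_size, lr, seed) {
  n <- model$n
  nc <- model$num_classes
  y <- one_hot(labels, nc)
  nobs <- dim(x)[4]
  with_seed(seed, {
    weights <- list(st = model$stacker$net$weights,
                    sub = lapply(model$subnetworks, function(s)
                      list(enc = s$encoder$weights, top = s$topper$weights)))
    opt <- opt_init("adam", weights, lr = lr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nobs)
      for (start in seq(1L, nobs, by = batch_size)) {
        b <- ord[start:min(start + batch_size - 1L, nobs)]
        xb <- x[, , , b, drop = FALSE]
        yb <- y[b, , drop = FALSE]
        fwd <- lapply(seq_len(n), function(i) {
          model$subnetworks[[i]]$encoder$weights <- weights$sub[[i]]$enc
          model$subnetworks[[i]]$topper$weights <- weights$sub[[i]]$top
          subnet_forward_cached(model$subnetworks[[i]], xb)
        })
        feats <- do.call(cbind, lapply(fwd, `[[`, "p"))
        model$stacker$net$weights <- weights$st
        fs <- forward_network(model$stacker$net, feats, cache = TRUE)
        dz <- (fs$out - yb) / length(b)
        bs <- backward_network(model$stacker$net, fs, dz)
        gsub <- vector("list", n)
        for (i in seq_len(n)) {
          dp <- bs$dx[, ((i - 1L) * nc + 1L):(i * nc), drop = FALSE]
          p <- fwd[[i]]$p
          dzi <- p * (dp - rowSums(dp * p)) # softmax Jacobian
          bt <- backward_network(model$subnetworks[[i]]$topper,
                                 fwd[[i]]$ft, dzi)
          be <- backward_network(model$subnetworks[[i]]$encoder,
                                 fwd[[i]]$fe, bt$dx, final_preact = FALSE)
          gsub[[i]] <- list(enc = be$grads, top = bt$grads)
        }
        st <- opt_step(opt, weights, list(st = bs$grads, sub = gsub))
        weights <- st$weights
        opt <- st$opt
      }
    }
    model$stacker$net$weights <- weights$st
    for (i in seq_len(n)) {
      model$subnetworks[[i]]$encoder$weights <- weights$sub[[i]]$enc
      model$subnetworks[[i]]$topper$weights <- weights$sub[[i]]$top
    }
  })
  model
}

#' Predict classes with a RandNet ensemble
#'
#' Runs every subnetwork, concatenates their class-probability vectors and
#' passes them through the stacking head.  The predicted class is the
#' argmax of the stacked probabilities, breaking ties toward the lowest
#' class index.
#'
#' @param object A `randnet_ensemble`.
#' @param newdata Normalized batch array (s, s, 1, N) at the model's input
#'   size, or a dataset/list of raw images (normalized and resized first).
#' @param ... Unused.
#' @return List with `class` (integer 0-based ids) and `prob` (N x classes
#'   matrix; rows sum to 1).
#' @export
predict.randnet_ensemble <- function(object, newdata, ...) {
  x <- as_input_array(newdata, object$input_size)
  features <- do.call(cbind, lapply(object$subnetworks, predict, x))
  prob <- predict(object$stacker, features)
  list(class = max.col(prob, ties.method = "first") - 1L, prob = prob)
}

#' @export
print.randnet_ensemble <- function(x, ...) {
  cat(sprintf("<randnet_ensemble: %d subnetworks, input %dx%d, %d classes>\n",
              x$n, x$input_size, x$input_size, x$num_classes))
  cat("  stages:", paste(x$provenance$stages, collapse = " -> "), "\n")
  invisible(x)
}

subset_dataset <- function(dataset, idx) {
  labeled_dataset(dataset$images[idx], dataset$labels[idx],
                  dataset$class_names)
}

#' Cross-validated selection of the number of subnetworks
#'
#' For every candidate `n` in `grid` and every stratified fold, trains a
#' RandNet on the other folds and records held-out accuracy (overall
#' classification rate) and mean categorical cross-entropy.  The best `n`
#' maximizes mean validation accuracy; ties break toward the smaller
#' (cheaper) ensemble.  Each (candidate, fold) pair retrains from scratch.
#'
#' @param unlabeled Unlabeled pool.
#' @param labeled_train Labeled training pool ([labeled_dataset]).
#' @param grid Candidate subnetwork counts (default `config$grid`,
#'   full-scale 1..37 step 2).
#' @param k Folds (default `config$k_folds`).
#' @param config A [randnet_config()].
#' @param seed Integer seed.
#' @return A `randnet_selection`: `grid`, `mean_val_accuracy`,
#'   `mean_val_loss`, `fold_accuracy`/`fold_loss` matrices, `best_n`.
#' @export
select_num_subnetworks <- function(unlabeled, labeled_train, grid = NULL,
                                   k = NULL, config = randnet_config(),
                                   seed = NULL) {
  if (is.null(grid)) grid <- config$grid
  if (is.null(k)) k <- config$k_folds
  if (is.null(seed)) seed <- config$seed
  if (!length(grid)) stopf("grid must be non-empty")
  grid <- sort(as.integer(grid))
  labels <- labeled_train$labels
  folds <- stratified_kfold(labels, k, stage_seed(seed, "folds"),
                            n_class = length(labeled_train$class_names))
  acc <- matrix(NA_real_, length(grid), k,
                dimnames = list(paste0("n", grid), paste0("fold", seq_len(k))))
  loss <- acc
  for (gi in seq_along(grid)) {
    for (f in seq_len(k)) {
      tr <- which(folds$fold_assignments != f)
      va <- which(folds$fold_assignments == f)
      model <- train_randnet(unlabeled, subset_dataset(labeled_train, tr),
                             n = grid[gi], config = config,
                             seed = seed + 31L * gi + f)
      pred <- predict(model, subset_dataset(labeled_train, va))
      cm <- confusion_matrix(labels[va], pred$class,
                             num_classes = length(labeled_train$class_names))
      acc[gi, f] <- average_classification_rate(cm)
      loss[gi, f] <- categorical_ce_loss(
        one_hot(labels[va], model$num_classes), pred$prob) / length(va)
    }
  }
  mean_acc <- rowMeans(acc)
  structure(list(grid = grid,
                 mean_val_accuracy = unname(mean_acc),
                 mean_val_loss = unname(rowMeans(loss)),
                 fold_accuracy = acc, fold_loss = loss,
                 best_n = grid[which.max(mean_acc)]),
            class = "randnet_selection")
}

#' @export
print.randnet_selection <- function(x, ...) {
  cat("<randnet_selection>\n")
  print(data.frame(n = x$grid, mean_val_accuracy = x$mean_val_accuracy,
                   mean_val_loss = x$mean_val_loss))
  cat("best_n:", x$best_n, "\n")
  invisible(x)
}

#' Final fit on the training partition and one-shot holdout evaluation
#'
#' Splits the labeled pool with the stratified 75/25 rule, fits a RandNet
#' on the training partition with the configured number of subnetworks,
#' and evaluates it exactly once on the untouched test partition.  A
#' non-empty train/test intersection aborts the run.
#'
#' @param dataset Full labeled pool ([labeled_dataset]).
#' @param unlabeled Unlabeled pool.
#' @param config A [randnet_config()] (uses `n_subnetworks` and
#'   `split_fraction`).
#' @param seed Integer seed.
#' @return A `randnet_holdout`: `model`, `confusion` (test
#'   [confusion_matrix()]), `metrics` ([metrics_report()]), `split`,
#'   `test_predictions`.
#' @export
final_fit_and_holdout <- function(dataset, unlabeled,
                                  config = randnet_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  split <- stratified_split(dataset, config$split_fraction,
                            stage_seed(seed, "splits"),
                            n_class = length(dataset$class_names))
  if (length(intersect(split$train_indices, split$test_indices)))
    stopf("leak detected: train and test partitions overlap")
  model <- train_randnet(unlabeled, subset_dataset(dataset, split$train_indices),
                         n = config$n_subnetworks, config = config,
                         seed = seed)
  test <- subset_dataset(dataset, split$test_indices)
  pred <- predict(model, test)
  cm <- confusion_matrix(test$labels, pred$class,
                         num_classes = length(dataset$class_names),
                         class_names = dataset$class_names)
  structure(list(model = model, confusion = cm, metrics = metrics_report(cm),
                 split = split, test_predictions = pred),
            class = "randnet_holdout")
}

#' @export
print.randnet_holdout <- function(x, ...) {
  cat("<randnet_holdout>\n")
  print(x$metrics)
  invisible(x)
}
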