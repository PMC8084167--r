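#' Build the convolutional autoencoder
#'
#' The encoder is an AlexNet-flavoured stack of five convolution blocks
#' (default 16, 32, 64, 64, 32 filters, 3x3 kernels, ReLU) with three 2x2
#' max-pooling stages, so the spatial extent shrinks by a factor of 8 into
#' a spatial latent block.  The decoder mirrors it with nearest-neighbour
#' upsampling plus convolution and ends in a single-channel sigmoid layer,
#' so reconstructions match the input shape with values in (0, 1).  Input
#' channels are 1 (grayscale crops).
#'
#' @param input_size Image side length; must be a multiple of 8 (the total
#'   downsampling factor).  224 reproduces the full-scale configuration;
#'   smaller multiples give desk-scale models.
#' @param filters Five filter counts for the encoder blocks.
#' @param kernel Convolution kernel size (odd).
#' @param seed Optional seed for weight initialization.
#' @return An untrained `autoencoder_model`.
#' @examples
#' ae <- build_autoencoder(32, seed = 1)
#' ae$input_size
#' @export
build_autoencoder <- function(input_size, filters = c(16L, 32L, 64L, 64L, 32L),
                              kernel = 3L, seed = NULL) {
  if (!is_count(input_size, 8L) || input_size %% 8L != 0L)
    stopf("input_size must be a positive multiple of 8, got %s", input_size)
  if (length(filters) != 5L) stopf("filters must have length 5")
  f <- as.integer(filters)
  enc_layers <- list(
    layer_conv(f[1], kernel), layer_pool(),
    layer_conv(f[2], kernel), layer_pool(),
    layer_conv(f[3], kernel), layer_pool(),
    layer_conv(f[4], kernel),
    layer_conv(f[5], kernel))
  dec_layers <- list(
    layer_conv(f[4], kernel), layer_upsample(),
    layer_conv(f[3], kernel), layer_upsample(),
    layer_conv(f[2], kernel), layer_upsample(),
    layer_conv(f[1], kernel),
    layer_conv(1L, kernel, activation = "sigmoid"))
  s <- as.integer(input_size)
  seeds <- if (is.null(seed)) list(NULL, NULL) else list(seed, seed + 1L)
  encoder <- init_network(enc_layers, c(s, s, 1L), seeds[[1]])
  latent <- encoder$shapes[[length(enc_layers)]]
  decoder <- init_network(dec_layers, latent, seeds[[2]])
  structure(list(encoder = encoder, decoder = decoder, input_size = s,
                 filters = f, training_log = numeric(0)),
            class = "autoencoder_model")
}

as_input_array <- function(x, input_size) {
  if (is.array(x) && length(dim(x)) == 4L) {
    if (dim(x)[1] != input_size || dim(x)[2] != input_size)
      stopf("shape error: batch is %dx%d but the model expects %dx%d",
            dim(x)[1], dim(x)[2], input_size, input_size)
    return(x)
  }
  if (is.matrix(x)) x <- list(gray_image(x, image_domain(x)))
  dataset_to_array(x, input_size)
}

#' Reconstruct images through the autoencoder
#'
#' @param model An `autoencoder_model`.
#' @param images Normalized batch array (s, s, 1, N), a dataset, or a list
#'   of images (raw images are normalized and resized first).
#' @return Array (s, s, 1, N) of reconstructions in (0, 1).
#' @export
reconstruct <- function(model, images) {
  x <- as_input_array(images, model$input_size)
  forward_network(model$decoder, forward_network(model$encoder, x))
}

#' Pretrain the autoencoder on the unlabeled pool
#'
#' Minimizes the summed pixel-wise binary cross-entropy
#' ([pixelwise_bce_loss()]) with Adadelta.  Defaults follow the published
#' configuration: 10 epochs, batch size 128.  The per-epoch entries of
#' `training_log` report the summed loss divided by the number of images
#' seen in the epoch (a per-image mean of the summed objective).
#'
#' @param model An `autoencoder_model`.
#' @param unlabeled Unlabeled pool: `unlabeled_dataset`, list of images, or
#'   a normalized (s, s, 1, N) array.
#' @param epochs,batch_size Training schedule.
#' @param seed Optional seed controlling shuffling (restores caller RNG).
#' @return The trained `autoencoder_model` with `training_log` filled.
#' @export
train_autoencoder <- function(model, unlabeled, epochs = 10L,
                              batch_size = 128L, seed = NULL) {
  if (!is_count(epochs)) stopf("epochs must be a non-negative integer")
  x <- as_input_array(unlabeled, model$input_size)
  n <- dim(x)[4]
  if (n == 0L) stopf("data error: empty unlabeled pool")
  if (epochs == 0L) return(model)
  with_seed(seed, {
    weights <- list(enc = model$encoder$weights, dec = model$decoder$weights)
    opt <- opt_init("adadelta", weights)
    log <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = batch_size)) {
        b <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[, , , b, drop = FALSE]
        model$encoder$weights <- weights$enc
        model$decoder$weights <- weights$dec
        fe <- forward_network(model$encoder, xb, cache = TRUE)
        fd <- forward_network(model$decoder, fe$out, cache = TRUE)
        total <- total + pixelwise_bce_loss(xb, fd$out)
        dz <- (fd$out - xb) / length(b)
        bd <- backward_network(model$decoder, fd, dz)
        be <- backward_network(model$encoder, fe, bd$dx, final_preact = FALSE)
        st <- opt_step(opt, weights, list(enc = be$grads, dec = bd$grads))
        weights <- st$weights
        opt <- st$opt
      }
      log[ep] <- total / n
    }
    model$encoder$weights <- weights$enc
    model$decoder$weights <- weights$dec
    model$training_log <- c(model$training_log, log)
  })
  model
}

#' Extract the pretrained encoder
#'
#' Returns an independent copy of the encoder (weights and layer spec);
#' its latent activations reproduce the autoencoder's exactly, and
#' mutating the copy leaves the autoencoder untouched.
#'
#' @param model A (trained) `autoencoder_model`.
#' @return An `encoder_model`.
#' @export
extract_encoder <- function(model) {
  structure(list(net = model$encoder, input_size = model$input_size),
            class = "encoder_model")
}

#' @rdname extract_encoder
#' @param encoder An `encoder_model`.
#' @param images Input batch (see [reconstruct()] for accepted forms).
#' @return `encode()`: the latent activation array (h, w, C, N).
#' @export
encode <- function(encoder, images) {
  x <- as_input_array(images, encoder$input_size)
  forward_network(encoder$net, x)
}

#' Build a subnetwork from a pretrained encoder
#'
#' A subnetwork is the (unfrozen) encoder followed by a topper head:
#' global average pooling, a ReLU dense layer, and a softmax output over
#' the classes.  Fine-tuning updates encoder and topper together, which is
#' what lets bootstrap subsets diversify the ensemble.
#'
#' @param encoder An `encoder_model` from [extract_encoder()].
#' @param num_classes Number of output classes (default 6).
#' @param hidden Width of the topper's dense layer.
#' @param pool How the spatial latent block enters the topper: `"gap"`
#'   (global average pooling, one feature per channel) or `"flatten"`
#'   (the full latent map as a vector; richer, used at desk scale where
#'   the latent block is small).
#' @param seed Optional seed for topper initialization.
#' @return A `subnetwork_model`.
#' @export
build_subnetwork <- function(encoder, num_classes = 6L, hidden = 64L,
                             pool = c("gap", "flatten"), seed = NULL) {
  pool <- match.arg(pool)
  latent <- encoder$net$shapes[[length(encoder$net$layers)]]
  topper <- init_network(
    list(if (pool == "gap") layer_gap() else layer_flatten(),
         layer_dense(hidden, "relu"),
         layer_dense(num_classes, "softmax")),
    latent, seed)
  structure(list(encoder = encoder$net, topper = topper,
                 input_size = encoder$input_size,
                 num_classes = as.integer(num_classes),
                 training_log = NULL),
            class = "subnetwork_model")
}

#' @export
predict.subnetwork_model <- function(object, newdata, ...) {
  x <- as_input_array(newdata, object$input_size)
  forward_network(object$topper, forward_network(object$encoder, x))
}

subnet_forward_cached <- function(subnet, xb) {
  fe <- forward_network(subnet$encoder, xb, cache = TRUE)
  ft <- forward_network(subnet$topper, fe$out, cache = TRUE)
  list(fe = fe, ft = ft, p = ft$out)
}

#' Fine-tune a subnetwork on a bootstrap subset
#'
#' Updates all weights (encoder included) by Adam on the summed categorical
#' cross-entropy ([categorical_ce_loss()]).  Defaults follow the published
#' configuration: 25 epochs with early stopping, batch size 50, learning
#' rate 0.001.  When `validation` is supplied, training stops once the
#' validation loss has not improved for `patience` epochs and the best
#' weights are restored.
#'
#' @param subnet A `subnetwork_model`.
#' @param images Training batch (array, dataset, or image list).
#' @param labels Integer class labels (0-based), parallel to `images`.
#' @param epochs,batch_size,lr,patience Training schedule.
#' @param validation Optional `list(images =, labels =)` held-out set for
#'   early stopping.
#' @param seed Optional seed controlling shuffling.
#' @return The fine-tuned `subnetwork_model`; `training_log` is a data
#'   frame of per-epoch mean train (and validation) losses.
#' @export
fine_tune_subnetwork <- function(subnet, images, labels, epochs = 25L,
                                 batch_size = 50L, lr = 0.001,
                                 patience = 5L, validation = NULL,
                                 seed = NULL) {
  if (!is_count(epochs)) stopf("epochs must be a non-negative integer")
  x <- as_input_array(images, subnet$input_size)
  n <- dim(x)[4]
  if (n == 0L) stopf("data error: empty training subset")
  labels <- as.integer(labels)
  if (length(labels) != n) stopf("labels do not match the batch size")
  y <- one_hot(labels, subnet$num_classes)
  if (epochs == 0L) return(subnet)
  xv <- NULL
  if (!is.null(validation)) {
    xv <- as_input_array(validation$images, subnet$input_size)
    yv <- one_hot(as.integer(validation$labels), subnet$num_classes)
  }
  with_seed(seed, {
    weights <- list(enc = subnet$encoder$weights, top = subnet$topper$weights)
    opt <- opt_init("adam", weights, lr = lr)
    best <- list(loss = Inf, weights = weights, wait = 0L)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = batch_size)) {
        b <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[, , , b, drop = FALSE]
        yb <- y[b, , drop = FALSE]
        subnet$encoder$weights <- weights$enc
        subnet$topper$weights <- weights$top
        fwd <- subnet_forward_cached(subnet, xb)
        total <- total + categorical_ce_loss(yb, fwd$p)
        dz <- (fwd$p - yb) / length(b)
        bt <- backward_network(subnet$topper, fwd$ft, dz)
        be <- backward_network(subnet$encoder, fwd$fe, bt$dx,
                               final_preact = FALSE)
        st <- opt_step(opt, weights, list(enc = be$grads, top = bt$grads))
        weights <- st$weights
        opt <- st$opt
      }
      subnet$encoder$weights <- weights$enc
      subnet$topper$weights <- weights$top
      val <- NA_real_
      if (!is.null(xv)) {
        val <- categorical_ce_loss(yv, predict(subnet, xv)) / dim(xv)[4]
        if (val < best$loss - 1e-9) {
          best$loss <- val
          best$weights <- weights
          best$wait <- 0L
        } else {
          best$wait <- best$wait + 1L
        }
      }
      log <- rbind(log, data.frame(epoch = ep, train_loss = total / n,
                                   val_loss = val))
      if (!is.null(xv) && best$wait >= patience) break
    }
    if (!is.null(xv) && is.finite(best$loss)) {
      subnet$encoder$weights <- best$weights$enc
      subnet$topper$weights <- best$weights$top
    }
    subnet$training_log <- log
  })
  subnet
}

#' Build the stacking network
#'
#' The fusion head that turns the concatenated class-probability vectors of
#' the `n` subnetworks (input dimension `n * num_classes`) into the final
#' decision; deliberately simple, with two main dense layers (ReLU hidden
#' layer, softmax output).
#'
#' @param n Number of subnetworks feeding the head (>= 1).
#' @param num_classes Number of classes (default 6).
#' @param hidden Hidden layer width.
#' @param seed Optional seed for initialization.
#' @return A `stacking_model` with `input_dim = n * num_classes`.
#' @examples
#' build_stacking_network(33)$input_dim  # 198
#' @export
build_stacking_network <- function(n, num_classes = 6L, hidden = 64L,
                                   seed = NULL) {
  if (!is_count(n, 1L)) stopf("config error: n must be a positive integer")
  net <- init_network(
    list(layer_dense(hidden, "relu"), layer_dense(num_classes, "softmax")),
    as.integer(n * num_classes), seed)
  structure(list(net = net, n = as.integer(n),
                 num_classes = as.integer(num_classes),
                 input_dim = as.integer(n * num_classes)),
            class = "stacking_model")
}

#' @export
predict.stacking_model <- function(object, newdata, ...) {
  if (ncol(newdata) != object$input_dim)
    stopf("shape error: stacking input has %d columns, expected %d",
          ncol(newdata), object$input_dim)
  forward_network(object$net, newdata)
}

# Train the stacking head by Adam on summed categorical cross-entropy.
train_stacking <- function(stacker, features, labels, epochs = 25L,
                           batch_size = 50L, lr = 0.001, seed = NULL) {
  n <- nrow(features)
  y <- one_hot(as.integer(labels), stacker$num_classes)
  if (epochs == 0L || n == 0L) return(stacker)
  with_seed(seed, {
    weights <- stacker$net$weights
    opt <- opt_init("adam", weights, lr = lr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        b <- ord[start:min(start + batch_size - 1L, n)]
        xb <- features[b, , drop = FALSE]
        yb <- y[b, , drop = FALSE]
        stacker$net$weights <- weights
        fw <- forward_network(stacker$net, xb, cache = TRUE)
        dz <- (fw$out - yb) / length(b)
        bk <- backward_network(stacker$net, fw, dz)
        st <- opt_step(opt, weights, bk$grads)
        weights <- st$weights
        opt <- st$opt
      }
    }
    stacker$net$weights <- weights
  })
  stacker
}
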