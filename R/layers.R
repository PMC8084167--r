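# Minimal trainable-network engine.  A network is an ordered list of layer
# descriptors plus a parallel list of weights; batches flow through as
# (H, W, C, N) arrays for spatial layers and (N, features) matrices after
# global pooling.  Convolutions are stride-1 'same'; pooling is 2x2 max;
# upsampling is x2 nearest-neighbour (see src/nn_ops.cpp).

layer_conv <- function(filters, kernel = 3L,
                       activation = c("relu", "sigmoid", "linear")) {
  list(kind = "conv", filters = as.integer(filters), kernel = as.integer(kernel),
       activation = match.arg(activation))
}
layer_pool <- function() list(kind = "pool")
layer_upsample <- function() list(kind = "upsample")
layer_gap <- function() list(kind = "gap")
layer_flatten <- function() list(kind = "flatten")
layer_dense <- function(units, activation = c("relu", "softmax", "linear")) {
  list(kind = "dense", units = as.integer(units),
       activation = match.arg(activation))
}

act_code <- function(a) switch(a, linear = 0L, relu = 1L, sigmoid = 2L,
                               stopf("no conv activation '%s'", a))

# Walk the layer list from input_shape, checking consistency and returning
# the shape after every layer.  Spatial shapes are c(H, W, C); dense-side
# shapes are a single integer (feature count).
network_shapes <- function(layers, input_shape) {
  shape <- input_shape
  shapes <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    shape <- switch(ly$kind,
      conv = {
        if (length(shape) != 3L) stopf("conv layer %d needs spatial input", i)
        c(shape[1], shape[2], ly$filters)
      },
      pool = {
        if (length(shape) != 3L || shape[1] %% 2L || shape[2] %% 2L)
          stopf("pool layer %d needs even spatial input, got %s", i,
                paste(shape, collapse = "x"))
        c(shape[1] %/% 2L, shape[2] %/% 2L, shape[3])
      },
      upsample = {
        if (length(shape) != 3L) stopf("upsample layer %d needs spatial input", i)
        c(shape[1] * 2L, shape[2] * 2L, shape[3])
      },
      gap = {
        if (length(shape) != 3L) stopf("gap layer %d needs spatial input", i)
        shape[3]
      },
      flatten = {
        if (length(shape) != 3L) stopf("flatten layer %d needs spatial input", i)
        prod(shape)
      },
      dense = {
        if (length(shape) != 1L) stopf("dense layer %d needs vector input", i)
        ly$units
      },
      stopf("unknown layer kind '%s'", ly$kind))
    shapes[[i]] <- shape
  }
  shapes
}

# He-uniform init for relu layers, Glorot-uniform otherwise; biases zero.
init_network <- function(layers, input_shape, seed = NULL) {
  shapes <- network_shapes(layers, input_shape)
  weights <- with_seed(seed, {
    shape <- input_shape
    w <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      if (ly$kind == "conv") {
        k <- ly$kernel; cin <- shape[3]; f <- ly$filters
        fan_in <- k * k * cin
        lim <- if (ly$activation == "relu") sqrt(6 / fan_in)
               else sqrt(6 / (fan_in + k * k * f))
        w[[i]] <- list(W = array(runif(k * k * cin * f, -lim, lim),
                                 dim = c(k, k, cin, f)),
                       b = numeric(f))
      } else if (ly$kind == "dense") {
        fan_in <- shape[1]
        lim <- if (ly$activation == "relu") sqrt(6 / fan_in)
               else sqrt(6 / (fan_in + ly$units))
        w[[i]] <- list(W = matrix(runif(fan_in * ly$units, -lim, lim),
                                  fan_in, ly$units),
                       b = numeric(ly$units))
      }
      shape <- shapes[[i]]
    }
    w
  })
  structure(list(layers = layers, weights = weights,
                 input_shape = input_shape, shapes = shapes),
            class = "nn_network")
}

row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass.  With cache = TRUE returns list(out, inputs, outputs, idx)
# for use by backward_network(); otherwise just the output.
forward_network <- function(net, x, cache = FALSE) {
  n_layer <- length(net$layers)
  inputs <- if (cache) vector("list", n_layer)
  outputs <- if (cache) vector("list", n_layer)
  idxs <- if (cache) vector("list", n_layer)
  for (i in seq_len(n_layer)) {
    ly <- net$layers[[i]]
    if (cache) inputs[[i]] <- x
    if (ly$kind == "conv") {
      x <- nn_conv_forward(x, net$weights[[i]]$W, net$weights[[i]]$b,
                           act_code(ly$activation))
    } else if (ly$kind == "pool") {
      r <- nn_maxpool_forward(x)
      x <- r$y
      if (cache) idxs[[i]] <- r$idx
    } else if (ly$kind == "upsample") {
      x <- nn_upsample_forward(x)
    } else if (ly$kind == "gap") {
      d <- dim(x)
      x <- t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])),
                    d[3], d[4]))
    } else if (ly$kind == "flatten") {
      d <- dim(x)
      x <- t(matrix(x, d[1] * d[2] * d[3], d[4]))
    } else { # dense
      z <- x %*% net$weights[[i]]$W
      z <- sweep(z, 2L, net$weights[[i]]$b, "+")
      x <- switch(ly$activation,
                  relu = pmax(z, 0),
                  softmax = row_softmax(z),
                  linear = z)
    }
    if (cache) outputs[[i]] <- x
  }
  if (cache) list(out = x, inputs = inputs, outputs = outputs, idx = idxs)
  else x
}

# Backward pass.  With final_preact = TRUE, `dz` is the gradient wrt the
# PRE-activation of the final layer (softmax+CCE gives p - y; sigmoid+BCE
# gives K - I) and the final activation derivative is skipped; with
# final_preact = FALSE, `dz` is the gradient wrt the activated output (used
# when backprop continues from a downstream network).  Returns
# list(grads, dx).
backward_network <- function(net, fw, dz, final_preact = TRUE) {
  n_layer <- length(net$layers)
  grads <- vector("list", n_layer)
  g <- dz
  for (i in rev(seq_len(n_layer))) {
    ly <- net$layers[[i]]
    xin <- fw$inputs[[i]]
    out <- fw$outputs[[i]]
    last <- (i == n_layer) && final_preact
    if (ly$kind == "conv") {
      acode <- if (last) 0L else act_code(ly$activation)
      r <- nn_conv_backward(xin, net$weights[[i]]$W, out, g, acode)
      grads[[i]] <- list(W = r$dw, b = as.numeric(r$db))
      g <- r$dx
    } else if (ly$kind == "pool") {
      d <- dim(xin)
      g <- nn_maxpool_backward(g, fw$idx[[i]], d[1], d[2])
    } else if (ly$kind == "upsample") {
      g <- nn_upsample_backward(g)
    } else if (ly$kind == "gap") {
      d <- dim(xin)
      g <- array(rep(as.vector(t(g)) / (d[1] * d[2]), each = d[1] * d[2]),
                 dim = d)
    } else if (ly$kind == "flatten") {
      g <- array(t(g), dim = dim(xin))
    } else { # dense
      dzl <- if (last) g
             else switch(ly$activation,
                         relu = g * (out > 0),
                         linear = g,
                         stopf("softmax only supported as final layer"))
      grads[[i]] <- list(W = crossprod(xin, dzl), b = colSums(dzl))
      g <- dzl %*% t(net$weights[[i]]$W)
    }
  }
  list(grads = grads, dx = g)
}
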