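# Shared fixtures and independent oracles, built in code at test time.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "randnet")
  if (!nzchar(p)) stop("fixture not found: ", name)
  p
}

# tiny 16-pixel pools for fast structural tests
tiny_pools <- function() {
  cached("tiny_pools", generate_dataset(synthetic_config(
    image_size = 16L, counts_per_class = rep(12L, 6),
    unlabeled_count = 48L, noise_sd = 0.02, seed = 99L)))
}

tiny_config <- function(...) {
  randnet_config(input_size = 16L, filters = c(4L, 8L, 8L, 8L, 8L),
                 ae_epochs = 1L, ae_batch = 16L, subnet_epochs = 2L,
                 subnet_batch = 24L, patience = 2L, stacker_epochs = 3L,
                 topper_pool = "flatten", n_subnetworks = 3L,
                 grid = c(1L, 2L), k_folds = 2L, ...)
}

tiny_ensemble <- function() {
  cached("tiny_ensemble", {
    pools <- tiny_pools()
    train_randnet(pools$unlabeled, pools$labeled, n = 3L,
                  config = tiny_config(), seed = 5L)
  })
}

# 4-neighbour connected-component count of a logical mask (independent
# oracle for the bleb-count property)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start_i in seq_len(nrow(mask))) {
    for (start_j in seq_len(ncol(mask))) {
      if (!mask[start_i, start_j] || lab[start_i, start_j] > 0L) next
      comp <- comp + 1L
      queue <- list(c(start_i, start_j))
      lab[start_i, start_j] <- comp
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          q <- p + d
          if (q[1] >= 1L && q[1] <= nrow(mask) && q[2] >= 1L &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- comp
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  comp
}

# plain k-nearest-neighbour vote on row-vector matrices
knn_predict <- function(train, train_labels, test, k = 5L) {
  apply(test, 1L, function(v) {
    d <- sqrt(rowSums(sweep(train, 2L, v)^2))
    votes <- train_labels[order(d)[seq_len(k)]]
    as.integer(names(which.max(table(votes))))
  })
}

# independent scalar-loop oracles for the two losses
bce_oracle <- function(targets, recon, eps = 1e-7) {
  total <- 0
  it <- as.vector(targets); kt <- as.vector(recon)
  for (i in seq_along(it)) {
    k <- min(max(kt[i], eps), 1 - eps)
    total <- total - (it[i] * log(k) + (1 - it[i]) * log(1 - k))
  }
  total
}

cce_oracle <- function(y, p, eps = 1e-7) {
  total <- 0
  for (i in seq_len(nrow(y)))
    for (j in seq_len(ncol(y))) {
      pc <- min(max(p[i, j], eps), 1 - eps)
      total <- total - y[i, j] * log(pc)
    }
  total
}

# independent scalar-loop bicubic resampler (Keys a = -0.5, centre-aligned,
# replicated edges) used as the oracle for the C++ implementation
bicubic_oracle <- function(img, out_h, out_w) {
  a <- -0.5
  kern <- function(t) {
    t <- abs(t)
    if (t <= 1) (a + 2) * t^3 - (a + 3) * t^2 + 1
    else if (t < 2) a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a
    else 0
  }
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, out_h, out_w)
  for (i in seq_len(out_h)) {
    sy <- (i - 0.5) * H / out_h - 0.5
    y0 <- floor(sy)
    for (j in seq_len(out_w)) {
      sx <- (j - 0.5) * W / out_w - 0.5
      x0 <- floor(sx)
      acc <- 0
      for (ti in 0:3) {
        ii <- min(max(y0 - 1 + ti, 0), H - 1)
        wy <- kern(sy - (y0 - 1 + ti))
        for (tj in 0:3) {
          jj <- min(max(x0 - 1 + tj, 0), W - 1)
          acc <- acc + wy * kern(sx - (x0 - 1 + tj)) * img[ii + 1, jj + 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

published_class_counts <- c(636L, 773L, 519L, 704L, 413L, 514L)
published_test_counts <- c(159L, 193L, 129L, 176L, 103L, 128L)
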