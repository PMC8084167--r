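# Adadelta and Adam on the nested weight lists used by nn_network objects.
# Weights/grads are flattened to parallel lists of numeric arrays so the
# update rules are written once.

flatten_weights <- function(w) {
  arrays <- list()
  skel <- (function() {
    rec <- function(x) {
      if (is.null(x)) return(NULL)
      if (is.list(x)) return(lapply(x, rec))
      arrays[[length(arrays) + 1L]] <<- x
      length(arrays)
    }
    rec
  })()
  skeleton <- skel(w)
  list(arrays = arrays, skeleton = skeleton)
}

unflatten_weights <- function(arrays, skeleton) {
  rec <- function(s) {
    if (is.null(s)) return(NULL)
    if (is.list(s)) return(lapply(s, rec))
    arrays[[s]]
  }
  rec(skeleton)
}

#' Gradient-descent optimizer state
#'
#' Creates optimizer state matched to a weight structure.  `"adadelta"`
#' follows the original parameter-free rule (decay rho, numerical eps;
#' the default autoencoder optimizer); `"adam"` is the default fine-tuning
#' optimizer with learning rate 0.001.
#'
#' @param kind `"adadelta"` or `"adam"`.
#' @param weights Nested weight list (as held by the network objects).
#' @param lr Learning rate (Adadelta applies it as a global scale, 1 by
#'   default; Adam default 0.001).
#' @param rho Adadelta decay rate.
#' @param beta1,beta2 Adam moment decays.
#' @param eps Numerical floor.
#' @return An `nn_optimizer` object.
#' @keywords internal
opt_init <- function(kind = c("adadelta", "adam"), weights, lr = NULL,
                     rho = 0.95, beta1 = 0.9, beta2 = 0.999, eps = NULL) {
  kind <- match.arg(kind)
  fl <- flatten_weights(weights)
  zeros <- lapply(fl$arrays, function(a) a * 0)
  if (kind == "adadelta") {
    structure(list(kind = kind, lr = if (is.null(lr)) 1.0 else lr, rho = rho,
                   eps = if (is.null(eps)) 1e-6 else eps,
                   acc_g = zeros, acc_dx = zeros, skeleton = fl$skeleton),
              class = "nn_optimizer")
  } else {
    structure(list(kind = kind, lr = if (is.null(lr)) 1e-3 else lr,
                   beta1 = beta1, beta2 = beta2,
                   eps = if (is.null(eps)) 1e-8 else eps,
                   m = zeros, v = zeros, t = 0L, skeleton = fl$skeleton),
              class = "nn_optimizer")
  }
}

# One update step; returns list(weights, opt).
opt_step <- function(opt, weights, grads) {
  w <- flatten_weights(weights)$arrays
  g <- flatten_weights(grads)$arrays
  if (opt$kind == "adadelta") {
    for (i in seq_along(w)) {
      opt$acc_g[[i]] <- opt$rho * opt$acc_g[[i]] + (1 - opt$rho) * g[[i]]^2
      step <- -sqrt(opt$acc_dx[[i]] + opt$eps) /
               sqrt(opt$acc_g[[i]] + opt$eps) * g[[i]]
      opt$acc_dx[[i]] <- opt$rho * opt$acc_dx[[i]] + (1 - opt$rho) * step^2
      w[[i]] <- w[[i]] + opt$lr * step
    }
  } else {
    opt$t <- opt$t + 1L
    bc1 <- 1 - opt$beta1^opt$t
    bc2 <- 1 - opt$beta2^opt$t
    for (i in seq_along(w)) {
      opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g[[i]]
      opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g[[i]]^2
      w[[i]] <- w[[i]] - opt$lr * (opt$m[[i]] / bc1) /
        (sqrt(opt$v[[i]] / bc2) + opt$eps)
    }
  }
  list(weights = unflatten_weights(w, opt$skeleton), opt = opt)
}
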