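#' Pixel-wise binary cross-entropy reconstruction loss
#'
#' The autoencoder's loss: for a batch of target images \eqn{I^{(i)}} and
#' reconstructions \eqn{K^{(i)}} (both on \[0, 1\]),
#' \deqn{L = -\sum_i \sum_r \sum_c I \log K + (1 - I)\log(1 - K),}
#' a sum over every pixel of every image in the batch (not a mean).
#' Reconstructions are clipped to \[eps, 1 - eps\] before the logs.
#'
#' @param targets,reconstructions Numeric arrays of identical shape with
#'   values in \[0, 1\] (any layout; summation runs over all elements).
#' @param eps Clipping constant for log-domain safety.
#' @return Non-negative scalar, the summed loss.
#' @examples
#' I <- matrix(c(1, 0, 0, 1), 2)
#' K <- matrix(c(0.8, 0.3, 0.2, 0.9), 2)
#' pixelwise_bce_loss(I, K)  # -(log .8 + log .8 + log .7 + log .9)
#' @export
pixelwise_bce_loss <- function(targets, reconstructions, eps = 1e-7) {
  if (!identical(dim2(targets), dim2(reconstructions)))
    stopf("shape mismatch between targets and reconstructions")
  if (min(targets) < 0 || max(targets) > 1)
    stopf("targets must lie in [0, 1]")
  k <- pmin(pmax(reconstructions, eps), 1 - eps)
  -sum(targets * log(k) + (1 - targets) * log(1 - k))
}

#' Categorical cross-entropy classification loss
#'
#' The subnetwork/stacking loss: for one-hot targets \eqn{y_{ij}} and
#' predicted class probabilities \eqn{p_{ij}} over M classes,
#' \deqn{L = -\sum_i \sum_j y_{ij} \log p_{ij},}
#' summed over the batch.  Probabilities are clipped to \[eps, 1 - eps\].
#'
#' @param y Numeric matrix (samples x classes) of one-hot rows.
#' @param p Numeric matrix of the same shape; rows are probability vectors.
#' @param eps Clipping constant.
#' @return Non-negative scalar, the summed loss.
#' @examples
#' y <- diag(3)[, c(1, 2, 3)]
#' categorical_ce_loss(diag(3), matrix(1/3, 3, 3))  # 3 * log(3)
#' @export
categorical_ce_loss <- function(y, p, eps = 1e-7) {
  if (!identical(dim2(y), dim2(p)))
    stopf("shape mismatch between y and p")
  if (!all(y %in% c(0, 1)) || !all(abs(rowSums(y) - 1) < 1e-9))
    stopf("label error: rows of y must be one-hot")
  pc <- pmin(pmax(p, eps), 1 - eps)
  -sum(y * log(pc))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

one_hot <- function(labels, n_class) {
  y <- matrix(0, length(labels), n_class)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}
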