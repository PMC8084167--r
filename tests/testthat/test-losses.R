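test_that("pixel-wise BCE matches hand-computed and closed-form values", {
  I <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  K <- matrix(c(0.8, 0.2, 0.3, 0.9), 2, byrow = TRUE)
  expect_equal(pixelwise_bce_loss(I, K),
               -(log(0.8) + log(0.8) + log(0.7) + log(0.9)),
               tolerance = 1e-12)

  # K constant 0.5 gives NR*NC*log(2) per image
  I2 <- array(sample(c(0, 1), 3 * 5 * 4, replace = TRUE), dim = c(3, 5, 1, 4))
  K2 <- array(0.5, dim = dim(I2))
  expect_equal(pixelwise_bce_loss(I2, K2), 4 * 3 * 5 * log(2),
               tolerance = 1e-12)

  # perfect binary reconstruction is ~0 (bounded by the clipping constant)
  expect_lt(pixelwise_bce_loss(I2, I2), length(I2) * -log(1 - 1e-7) + 1e-9)
})

test_that("categorical CE matches hand-computed and closed-form values", {
  # uniform prediction costs log(6) per sample
  y <- diag(6)[c(3, 1, 5), ]
  expect_equal(categorical_ce_loss(y, matrix(1 / 6, 3, 6)), 3 * log(6),
               tolerance = 1e-12)

  # three samples with true-class probabilities 0.5, 0.25, 0.1
  p <- matrix(0.02, 3, 6)
  p[1, 3] <- 0.5; p[2, 1] <- 0.25; p[3, 5] <- 0.1
  expect_equal(categorical_ce_loss(y, p),
               -(log(0.5) + log(0.25) + log(0.1)), tolerance = 1e-12)

  expect_lt(categorical_ce_loss(y, y), 1e-5)
})

test_that("both losses agree with independent scalar-loop oracles", {
  set.seed(123)
  for (rep in 1:5) {
    I <- array(runif(6 * 6 * 1 * 3), dim = c(6, 6, 1, 3))
    K <- array(runif(6 * 6 * 1 * 3, 0.01, 0.99), dim = c(6, 6, 1, 3))
    expect_equal(pixelwise_bce_loss(I, K), bce_oracle(I, K),
                 tolerance = 1e-6)

    labs <- sample(0:5, 8, replace = TRUE)
    y <- diag(6)[labs + 1, ]
    raw <- matrix(runif(8 * 6), 8, 6)
    p <- raw / rowSums(raw)
    expect_equal(categorical_ce_loss(y, p), cce_oracle(y, p),
                 tolerance = 1e-6)
  }
})

test_that("loss preconditions are enforced", {
  expect_error(pixelwise_bce_loss(matrix(0, 2, 2), matrix(0.5, 3, 3)),
               "shape")
  expect_error(pixelwise_bce_loss(matrix(2, 2, 2), matrix(0.5, 2, 2)),
               "\\[0, 1\\]")
  expect_error(categorical_ce_loss(matrix(0.5, 2, 6), matrix(1 / 6, 2, 6)),
               "one-hot")
  expect_error(categorical_ce_loss(diag(6), matrix(1 / 6, 3, 6)), "shape")
})
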