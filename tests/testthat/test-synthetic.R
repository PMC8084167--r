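test_that("class images are deterministic in the seed and validate inputs", {
  a <- generate_class_image(3, 32, noise_sd = 0.05, seed = 7)
  b <- generate_class_image(3, 32, noise_sd = 0.05, seed = 7)
  expect_identical(unclass(a), unclass(b))
  d <- generate_class_image(3, 32, noise_sd = 0.05, seed = 8)
  expect_false(identical(unclass(a), unclass(d)))

  expect_error(generate_class_image(6, 64), "class_id")
  expect_error(generate_class_image(-1, 64), "class_id")
  expect_error(generate_class_image(2, 8), "image_size")
  expect_error(generate_class_image(2, 64, separability = 0), "separability")
})

test_that("unattached-cell renders carry a bright halo above background", {
  for (seed in 1:5) {
    img <- generate_class_image(2, 64, noise_sd = 0, separability = 1,
                                seed = seed)
    # halo ring contrast is 0.45 on the normalized scale over a 0.5 background
    expect_gte(max(img) - 127.5, 0.44 * 255 * 0.95)
  }
})

test_that("apoptotically blebbing cells show >= 8 disjoint boundary blebs", {
  for (seed in 1:5) {
    img <- unclass(generate_class_image(5, 64, noise_sd = 0, seed = seed)) / 255
    s <- nrow(img)
    ax <- seq(-1, 1, length.out = s)
    D <- sqrt(outer(ax^2, ax^2, "+"))
    band <- D > 0.14 & D < 0.40 # boundary band around the body radius
    mask <- band & img > 0.80   # above body intensity, below bleb peaks
    expect_gte(count_components(mask), 8L)
  }
})

test_that("foreground intensity orders unattached above attached every seed", {
  centre <- 25:40 # central block of a 64-pixel image
  for (seed in 1:10) {
    un <- generate_class_image(2, 64, noise_sd = 0.02, seed = seed)
    at <- generate_class_image(3, 64, noise_sd = 0.02, seed = seed)
    expect_gt(mean(unclass(un)[centre, centre]),
              mean(unclass(at)[centre, centre]))
  }
})

test_that("generate_dataset emits the configured counts", {
  ds <- generate_dataset(synthetic_config(
    image_size = 16, counts_per_class = rep(10L, 6), unlabeled_count = 100L,
    seed = 3))
  expect_length(ds$labeled$images, 60L)
  expect_identical(tabulate(ds$labeled$labels + 1L, 6L), rep(10L, 6))
  expect_length(ds$unlabeled$images, 100L)

  empty <- generate_dataset(synthetic_config(
    image_size = 16, counts_per_class = rep(0L, 6), unlabeled_count = 5L))
  expect_length(empty$labeled$images, 0L)
  expect_length(empty$unlabeled$images, 5L)

  full_sized <- generate_dataset(synthetic_config(
    image_size = 16, counts_per_class = published_class_counts,
    unlabeled_count = 0L, seed = 4))
  expect_length(full_sized$labeled$images, 3559L)
})

test_that("identical configs give bit-identical datasets", {
  cfg <- synthetic_config(image_size = 16, counts_per_class = rep(3L, 6),
                          unlabeled_count = 6L, seed = 21)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  for (i in seq_along(a$labeled$images))
    expect_identical(unclass(a$labeled$images[[i]]),
                     unclass(b$labeled$images[[i]]))
  for (i in seq_along(a$unlabeled$images))
    expect_identical(unclass(a$unlabeled$images[[i]]),
                     unclass(b$unlabeled$images[[i]]))
})

test_that("classes stay 5-NN separable on 16x16 downsampled pixels", {
  ds <- generate_dataset(synthetic_config(
    image_size = 64, counts_per_class = rep(60L, 6), unlabeled_count = 0L,
    noise_sd = 0.02, class_separability = 1, seed = 17))
  vecs <- t(vapply(ds$labeled$images, function(im)
    as.vector(unclass(normalize_and_resize(im, 16))), numeric(256)))
  labs <- ds$labeled$labels
  sp <- stratified_split(labs, 0.5, seed = 1)
  pred <- knn_predict(vecs[sp$train_indices, ], labs[sp$train_indices],
                      vecs[sp$test_indices, ], k = 5L)
  expect_gte(mean(pred == labs[sp$test_indices]), 0.80)
})
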