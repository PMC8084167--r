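test_that("confusion matrices tally with columns as the true class", {
  perfect <- rep(0:4, each = 2)
  cm <- confusion_matrix(perfect, perfect, num_classes = 5)
  expect_identical(sum(diag(as.matrix(cm))), 10L)
  expect_identical(sum(cm) - sum(diag(as.matrix(cm))), 0L)

  cm2 <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), num_classes = 2)
  expect_identical(cm2[1, 1], 1L) # counts[pred=0, true=0]
  expect_identical(cm2[2, 1], 1L) # counts[pred=1, true=0]
  expect_identical(cm2[2, 2], 1L)

  set.seed(61)
  for (rep in 1:5) {
    t <- sample(0:5, 100, replace = TRUE)
    p <- sample(0:5, 100, replace = TRUE)
    cm3 <- confusion_matrix(t, p, num_classes = 6)
    expect_identical(as.integer(colSums(cm3)), tabulate(t + 1L, 6L))
    expect_identical(as.integer(rowSums(cm3)), tabulate(p + 1L, 6L))
    expect_identical(sum(cm3), 100L)
  }

  expect_error(confusion_matrix(c(0, 6), c(0, 0), num_classes = 6), "label")
  expect_error(confusion_matrix(c(0, 1), c(0), num_classes = 2), "length")
})

test_that("the published test matrix yields its printed accuracy and recalls", {
  cm <- read_confusion_matrix(fixture_path("cm_randnet_hesc_test.txt"))
  expect_identical(sum(cm), 888L)
  expect_identical(as.integer(colSums(cm)), published_test_counts)
  expect_equal(average_classification_rate(cm), 855 / 888, tolerance = 0)
  expect_equal(class_tpr(cm, 3), 173 / 176, tolerance = 0)
  expect_equal(class_tpr(cm, 2), 121 / 129, tolerance = 0)
  expect_equal(class_tpr(cm, "attached_cell"), 173 / 176, tolerance = 0)

  rep <- metrics_report(cm)
  expect_equal(unname(round(rep$per_class_tpr, 4)),
               c(0.9686, 0.9689, 0.9380, 0.9830, 0.9417, 0.9609))
})

test_that("the Mask-RCNN-segmented matrix yields its printed metrics", {
  cm <- read_confusion_matrix(fixture_path("cm_randnet_maskrcnn_segments.txt"))
  expect_identical(sum(cm), 419L)
  expect_equal(average_classification_rate(cm), 393 / 419, tolerance = 0)
  rep <- metrics_report(cm)
  expect_equal(unname(round(rep$per_class_tpr, 4)),
               c(0.9043, 0.9333, 0.9841, 0.9753, 0.9487, 0.8955))
})

test_that("metrics are permutation-invariant and satisfy the ACR identity", {
  cm <- read_confusion_matrix(fixture_path("cm_randnet_hesc_test.txt"))
  perm <- c(4, 2, 6, 1, 3, 5)
  m <- as.matrix(cm)[perm, perm]
  cmp <- asNamespace("randnet")$as_confusion_matrix(m, colnames(cm)[perm])
  expect_equal(average_classification_rate(cmp),
               average_classification_rate(cm))
  expect_equal(unname(per_class_tpr(cmp)), unname(per_class_tpr(cm))[perm])

  # ACR equals the column-weighted mean of per-class TPRs
  w <- colSums(as.matrix(cm)) / sum(cm)
  expect_equal(average_classification_rate(cm),
               sum(per_class_tpr(cm) * w), tolerance = 1e-12)
  tpr <- per_class_tpr(cm)
  expect_true(all(tpr >= 0 & tpr <= 1))
  expect_gte(average_classification_rate(cm), min(tpr))
  expect_lte(average_classification_rate(cm), max(tpr))
})

test_that("degenerate matrices raise the documented errors", {
  empty <- asNamespace("randnet")$as_confusion_matrix(matrix(0L, 6, 6))
  expect_error(average_classification_rate(empty), "division")
  expect_error(class_tpr(empty, 0), "undefined-class")

  ident <- asNamespace("randnet")$as_confusion_matrix(diag(3L) * 5L)
  expect_equal(average_classification_rate(ident), 1.0)
  expect_equal(class_tpr(ident, 1), 1.0)
})
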