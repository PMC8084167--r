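#' Normalize and resize a raw image to network input scale
#'
#' Resizes a raw-domain \[0, 255\] image to `target_size` x `target_size`
#' with bicubic interpolation (Keys kernel, no anti-aliasing), clamps the
#' interpolation overshoot back into \[0, 255\], then divides by 255.  The
#' resize is done on raw values and the division applied afterwards.
#'
#' @param image A raw-domain [gray_image] (or plain matrix, taken as raw).
#' @param target_size Output side length in pixels.
#' @return A normalized-domain [gray_image] of size
#'   `target_size` x `target_size` with values in \[0, 1\].
#' @examples
#' img <- gray_image(matrix(255, 4, 4), "raw")
#' out <- normalize_and_resize(img, 8)
#' range(out)
#' @export
normalize_and_resize <- function(image, target_size) {
  image <- as_gray_image(image)
  if (image_domain(image) != "raw")
    stopf("normalize_and_resize() expects a raw-domain image")
  if (!is_count(target_size, 1L)) stopf("target_size must be a positive integer")
  px <- nn_bicubic_resize(unclass(image), as.integer(target_size),
                          as.integer(target_size))
  px <- pmin(pmax(px, 0), 255)
  gray_image(px / 255, "normalized")
}

# Stack a dataset (or list of images) into an (s, s, 1, N) normalized array.
dataset_to_array <- function(x, target_size) {
  images <- if (inherits(x, c("labeled_dataset", "unlabeled_dataset")))
    x$images else x
  n <- length(images)
  out <- array(0, dim = c(target_size, target_size, 1L, n))
  for (i in seq_len(n)) {
    img <- images[[i]]
    img <- if (image_domain(as_gray_image(img)) == "raw")
      normalize_and_resize(img, target_size)
    else {
      if (nrow(img) != target_size || ncol(img) != target_size)
        stopf("normalized image %d is not %dx%d", i, target_size, target_size)
      img
    }
    out[, , 1L, i] <- unclass(img)
  }
  out
}

dataset_labels <- function(x) {
  if (inherits(x, "labeled_dataset")) return(x$labels)
  as.integer(x)
}

class_pools <- function(labels, n_class = NULL) {
  if (is.null(n_class)) n_class <- max(labels) + 1L
  pools <- lapply(0:(n_class - 1L), function(cl) which(labels == cl))
  empty <- which(vapply(pools, length, integer(1)) == 0L)
  if (length(empty))
    stopf("stratification error: class %s has no samples",
          paste(empty - 1L, collapse = ", "))
  pools
}

#' Stratified train/test split
#'
#' Per class `c`, assigns `floor((1 - fraction) * count_c)` samples to the
#' test partition (drawn uniformly without replacement under `seed`) and
#' the remainder to training.  With the default `fraction = 0.75` this is
#' the 75/25 out-of-sample protocol; applied to class counts
#' (636, 773, 519, 704, 413, 514) it yields per-class test counts
#' (159, 193, 129, 176, 103, 128).
#'
#' @param dataset A [labeled_dataset] or an integer label vector (0-based).
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed for the draw.
#' @param n_class Number of classes (default: inferred).
#' @return A `split_plan`: `train_indices`, `test_indices` (1-based, into
#'   the dataset order), `fraction`, `per_class_test_counts`, `seed`.
#' @examples
#' labs <- rep(0:5, each = 4)
#' sp <- stratified_split(labs, 0.75, seed = 1)
#' sp$per_class_test_counts
#' @export
stratified_split <- function(dataset, fraction = 0.75, seed = 1L,
                             n_class = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stopf("fraction must lie in (0, 1)")
  labels <- dataset_labels(dataset)
  if (is.null(n_class) && inherits(dataset, "labeled_dataset"))
    n_class <- length(dataset$class_names)
  pools <- class_pools(labels, n_class)
  test <- integer(0)
  with_seed(seed, {
    for (pool in pools) {
      n_test <- floor((1 - fraction) * length(pool))
      if (n_test > 0) test <- c(test, sort(sample(pool, n_test)))
    }
  })
  test <- sort(test)
  train <- setdiff(seq_along(labels), test)
  per_class <- vapply(seq_along(pools), function(ci)
    sum(labels[test] == ci - 1L), integer(1))
  structure(list(train_indices = train, test_indices = test,
                 fraction = fraction,
                 per_class_test_counts = per_class,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Stratified bootstrap plan for the subnetworks
#'
#' Creates `n` bootstrap subsets of the training pool: for each subset and
#' each class, `size(class)` indices are drawn uniformly with replacement
#' from that class's pool (classical n-out-of-n bootstrap, stratified), so
#' every subset preserves the class composition of the training pool.
#'
#' @param train_labels Integer labels (0-based) of the training pool.
#' @param n Number of subsets (one per subnetwork), >= 1.
#' @param seed Integer seed.
#' @param n_class Number of classes (default: inferred).
#' @return A `bootstrap_plan`: `n`, `subsets` (list of `n` index vectors
#'   into `train_labels`), `seed`.
#' @export
stratified_bootstrap <- function(train_labels, n, seed = 1L, n_class = NULL) {
  if (!is_count(n, 1L)) stopf("n must be a positive integer")
  labels <- dataset_labels(train_labels)
  pools <- class_pools(labels, n_class)
  subsets <- with_seed(seed, lapply(seq_len(n), function(i)
    unlist(lapply(pools, function(pool)
      pool[sample.int(length(pool), length(pool), replace = TRUE)]),
      use.names = FALSE)))
  structure(list(n = as.integer(n), subsets = subsets,
                 seed = as.integer(seed)),
            class = "bootstrap_plan")
}

#' Stratified k-fold partition of the training pool
#'
#' Per class, samples are shuffled under `seed` and dealt round-robin into
#' `k` folds, so per-class fold sizes differ by at most one.
#'
#' @param train_labels Integer labels (0-based) of the training pool.
#' @param k Number of folds, >= 2 (default 5).
#' @param seed Integer seed.
#' @param n_class Number of classes (default: inferred).
#' @return A `fold_plan`: `k` and `fold_assignments` (integer in 1..k per
#'   training sample).
#' @export
stratified_kfold <- function(train_labels, k = 5L, seed = 1L, n_class = NULL) {
  if (!is_count(k, 2L)) stopf("k must be an integer >= 2")
  labels <- dataset_labels(train_labels)
  pools <- class_pools(labels, n_class)
  small <- which(vapply(pools, length, integer(1)) < k)
  if (length(small))
    stopf("fold error: class %s has fewer than k = %d samples",
          paste(small - 1L, collapse = ", "), k)
  assignments <- integer(length(labels))
  with_seed(seed, {
    for (pool in pools) {
      shuffled <- sample(pool)
      assignments[shuffled] <- rep_len(seq_len(k), length(pool))
    }
  })
  structure(list(k = as.integer(k), fold_assignments = assignments),
            class = "fold_plan")
}

#' Serialize or restore a split/bootstrap/fold plan as JSON
#'
#' @param plan A `split_plan`, `bootstrap_plan` or `fold_plan`.
#' @param path JSON file path.
#' @return `read_plan()` returns the restored plan object.
#' @export
write_plan <- function(plan, path) {
  obj <- c(list(.plan_class = class(plan)[1]), unclass(plan))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.plan_class
  obj$.plan_class <- NULL
  if (cls == "bootstrap_plan" && is.matrix(obj$subsets))
    obj$subsets <- lapply(seq_len(nrow(obj$subsets)), function(i) obj$subsets[i, ])
  for (f in c("train_indices", "test_indices", "fold_assignments",
              "per_class_test_counts", "n", "k", "seed"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.integer(obj[[f]])
  if (!is.null(obj$subsets)) obj$subsets <- lapply(obj$subsets, as.integer)
  structure(obj, class = cls)
}
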