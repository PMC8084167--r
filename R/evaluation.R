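#' Confusion matrix with true classes in columns
#'
#' Builds the count matrix `counts[pred + 1, true + 1]` from parallel label
#' vectors: columns index the TRUE class and rows the PREDICTED class, so
#' each column total equals the number of true-class samples evaluated and
#' the diagonal holds the correctly classified counts.
#'
#' @param true_labels,predicted_labels Equal-length integer vectors with
#'   values in `0..num_classes-1`.
#' @param num_classes Number of classes (default: inferred from the labels
#'   or `class_names`).
#' @param class_names Optional class names for the dimnames.
#' @return A `confusion_matrix` (classed integer matrix).
#' @examples
#' cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), num_classes = 2)
#' colSums(cm)  # per-class true counts
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             num_classes = NULL, class_names = NULL) {
  t <- as.integer(true_labels)
  p <- as.integer(predicted_labels)
  if (length(t) != length(p))
    stopf("label error: true and predicted labels differ in length")
  if (is.null(num_classes))
    num_classes <- if (!is.null(class_names)) length(class_names)
                   else max(c(t, p, 0L)) + 1L
  if (length(t) && (min(c(t, p)) < 0L || max(c(t, p)) >= num_classes))
    stopf("label error: labels outside 0..%d", num_classes - 1L)
  counts <- matrix(0L, num_classes, num_classes)
  for (i in seq_along(t))
    counts[p[i] + 1L, t[i] + 1L] <- counts[p[i] + 1L, t[i] + 1L] + 1L
  if (is.null(class_names) && num_classes == 6L)
    class_names <- hesc_class_names()
  if (!is.null(class_names))
    dimnames(counts) <- list(predicted = class_names, true = class_names)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

as_confusion_matrix <- function(counts, class_names = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stopf("confusion matrix must be square")
  if (any(counts < 0)) stopf("confusion matrix entries must be >= 0")
  storage.mode(counts) <- "integer"
  if (!is.null(class_names))
    dimnames(counts) <- list(predicted = class_names, true = class_names)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Read a confusion matrix from a plain-text fixture
#'
#' Accepts whitespace-separated integers, one predicted-class row per line
#' (columns = true class), with optional `#` comments and an optional
#' non-numeric header row.
#'
#' @param path Text file path.
#' @param class_names Class names (default the six hESC classes when the
#'   matrix is 6x6).
#' @return A `confusion_matrix`.
#' @export
read_confusion_matrix <- function(path, class_names = NULL) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  rows <- lapply(strsplit(lines, "\\s+"), function(tok) {
    suppressWarnings(as.numeric(tok))
  })
  rows <- rows[!vapply(rows, function(r) any(is.na(r)), logical(1))]
  if (!length(rows)) stopf("no numeric rows in %s", path)
  n <- length(rows[[1]])
  if (!all(lengths(rows) == n) || length(rows) != n)
    stopf("matrix in %s is not square", path)
  counts <- do.call(rbind, rows)
  if (is.null(class_names) && n == 6L) class_names <- hesc_class_names()
  as_confusion_matrix(counts, class_names)
}

#' Overall and per-class accuracy from a confusion matrix
#'
#' `average_classification_rate()` is the trace over the grand total,
#' \eqn{ACR = \sum_i CM_{ii} / N}.  `class_tpr()` is the per-class
#' recall/true-positive rate, the diagonal entry over its true-class
#' column total, \eqn{TPR_j = CM_{jj} / N_j}.  Both are exact rationals of
#' the counts; rounding happens only at presentation.
#'
#' @param cm A `confusion_matrix`.
#' @return `average_classification_rate()`: scalar in \[0, 1\].
#' @examples
#' cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), num_classes = 2)
#' average_classification_rate(cm)
#' class_tpr(cm, 0)
#' @export
average_classification_rate <- function(cm) {
  total <- sum(cm)
  if (total == 0) stopf("division error: empty confusion matrix")
  sum(diag(as.matrix(cm))) / total
}

#' @rdname average_classification_rate
#' @param j Class: a 0-based class id or a class name.
#' @export
class_tpr <- function(cm, j) {
  m <- as.matrix(cm)
  if (is.character(j)) {
    idx <- match(j, colnames(m))
    if (is.na(idx)) stopf("unknown class name '%s'", j)
  } else {
    if (!is_count(j) || j >= ncol(m)) stopf("class id out of range")
    idx <- as.integer(j) + 1L
  }
  nj <- sum(m[, idx])
  if (nj == 0) stopf("undefined-class error: no samples of class %s", j)
  m[idx, idx] / nj
}

#' @rdname average_classification_rate
#' @export
per_class_tpr <- function(cm) {
  m <- as.matrix(cm)
  out <- vapply(seq_len(ncol(m)), function(i) {
    nj <- sum(m[, i])
    if (nj == 0) NA_real_ else m[i, i] / nj
  }, numeric(1))
  names(out) <- colnames(m)
  out
}

#' Bundle the standard metrics of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return A `randnet_metrics` object: `acr`, `per_class_tpr` (named),
#'   `n_evaluated`.  Printing shows percentages rounded half-up to two
#'   decimals, matching tabular presentation; the stored values are exact.
#' @export
metrics_report <- function(cm) {
  structure(list(acr = average_classification_rate(cm),
                 per_class_tpr = per_class_tpr(cm),
                 n_evaluated = sum(cm)),
            class = "randnet_metrics")
}

#' @rdname metrics_report
#' @param x A `randnet_metrics` object.
#' @param ... Unused.
#' @export
print.randnet_metrics <- function(x, ...) {
  cat(sprintf("overall accuracy: %.2f%%  (n = %d)\n",
              round_half_up(100 * x$acr), x$n_evaluated))
  nm <- names(x$per_class_tpr)
  if (is.null(nm)) nm <- paste0("class_", seq_along(x$per_class_tpr) - 1L)
  for (i in seq_along(x$per_class_tpr))
    cat(sprintf("  %-20s %.2f%%\n", nm[i],
                round_half_up(100 * x$per_class_tpr[i])))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> columns = true class, rows = predicted class\n")
  print(unclass(x))
  invisible(x)
}

#' Write a metrics report and matrix to disk
#'
#' Writes the count matrix as CSV and the metrics (exact fractions plus
#' half-up two-decimal percentages) as JSON.
#'
#' @param cm A `confusion_matrix`.
#' @param dir Output directory.
#' @return The metrics list, invisibly.
#' @export
write_metrics <- function(cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(unclass(as.matrix(cm))),
            file.path(dir, "confusion_matrix.csv"))
  rep <- metrics_report(cm)
  out <- list(
    acr = rep$acr,
    acr_percent = round_half_up(100 * rep$acr),
    per_class_tpr = as.list(rep$per_class_tpr),
    per_class_tpr_percent = as.list(round_half_up(100 * rep$per_class_tpr)),
    n_evaluated = rep$n_evaluated)
  jsonlite::write_json(out, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
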