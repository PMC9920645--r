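#' Confusion matrix from true and predicted labels
#'
#' @param y_true,y_pred Integer label vectors of equal length.
#' @param n_classes Number of classes `m`; defaults to the largest label seen.
#' @return An `m x m` integer count matrix, rows = true class, columns =
#'   predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = max(y_true, y_pred)) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  cm
}

#' Micro-averaged precision, recall and accuracy
#'
#' Micro-averaging pools the per-class counts before forming ratios:
#' `micro_P = sum(TP_j) / sum(TP_j + FP_j)` and
#' `micro_R = sum(TP_j) / sum(TP_j + FN_j)`, with `TP_j` the diagonal,
#' `FP_j` the off-diagonal column sums and `FN_j` the off-diagonal row sums.
#' For single-label predictions both denominators equal the total count, so
#' micro-P, micro-R and accuracy coincide.
#'
#' @param confusion Square non-negative count matrix (rows = true class).
#' @return List with `micro_p`, `micro_r`, `accuracy`, and `degenerate`
#'   (TRUE when a zero denominator forced a metric to 0).
#' @export
micro_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion matrix must be non-negative")
  tp <- sum(diag(confusion))
  tp_fp <- sum(colSums(confusion))   # TP + FP pooled over classes
  tp_fn <- sum(rowSums(confusion))   # TP + FN pooled over classes
  total <- sum(confusion)
  degenerate <- (tp_fp == 0) || (tp_fn == 0) || (total == 0)
  if (degenerate) warning("zero denominator in micro metrics; reporting 0")
  list(
    micro_p = if (tp_fp > 0) tp / tp_fp else 0,
    micro_r = if (tp_fn > 0) tp / tp_fn else 0,
    accuracy = if (total > 0) tp / total else 0,
    degenerate = degenerate
  )
}

#' Full evaluation report
#'
#' Builds the confusion matrix and emits accuracy, micro- and macro-averaged
#' precision/recall, and the per-class TP/FP/FN counts. Macro averages are
#' included because reported precision and sensitivity that differ (as in
#' published multiclass gesture results) cannot both be micro-averages of a
#' single-label confusion matrix.
#'
#' @inheritParams confusion_matrix
#' @param class_names Optional class names.
#' @return A list of class `eval_report`.
#' @export
eval_report <- function(y_true, y_pred, n_classes = max(y_true, y_pred),
                        class_names = NULL) {
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  mm <- micro_metrics(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  structure(
    list(
      confusion = cm, accuracy = mm$accuracy,
      micro_p = mm$micro_p, micro_r = mm$micro_r,
      macro_p = mean(prec), macro_r = mean(rec),
      per_class = list(tp = as.integer(tp), fp = as.integer(fp),
                       fn = as.integer(fn)),
      class_names = class_names, degenerate = mm$degenerate
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d | accuracy %.4f | micro-P %.4f | micro-R %.4f | macro-P %.4f | macro-R %.4f\n",
    sum(x$confusion), x$accuracy, x$micro_p, x$micro_r, x$macro_p, x$macro_r
  ))
  invisible(x)
}

#' Write / read an evaluation report as JSON
#'
#' Counts round-trip exactly; real-valued metrics are written with full
#' precision.
#'
#' @param report An `eval_report`.
#' @param path JSON path.
#' @return `path` invisibly / the restored `eval_report`.
#' @export
write_eval_report <- function(report, path) {
  out <- report
  out$confusion <- unclass(out$confusion)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$confusion <- matrix(as.integer(raw$confusion),
                          nrow = nrow(raw$confusion))
  raw$per_class <- lapply(raw$per_class, as.integer)
  structure(raw, class = "eval_report")
}

#' Stratified train/test holdout split
#'
#' Per class, `round(frac * count)` observations go to the test set and the
#' rest to training; the draw is seed-deterministic, and the two index sets
#' are disjoint and exhaustive.
#'
#' @param y Integer label vector.
#' @param frac Test fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with integer vectors `train_idx` and `test_idx`.
#' @export
stratified_holdout <- function(y, frac, seed) {
  if (frac <= 0 || frac >= 1) stop("frac must lie in (0, 1)")
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      n_test <- round(frac * length(idx))
      if (n_test < 1 || n_test >= length(idx))
        stop(sprintf("class %d too small for a %.0f%% holdout", cl, 100 * frac))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  list(train_idx = setdiff(seq_along(y), test_idx), test_idx = test_idx)
}

#' Stratified k-fold assignment
#'
#' Per class, indices are shuffled (seed-deterministic) and dealt round-robin
#' to folds, so per-class fold sizes differ by at most one.
#'
#' @param y Integer label vector.
#' @param folds Number of folds, `2 <= folds <=` smallest class count.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..folds`, one per observation.
#' @export
kfold_stratified <- function(y, folds, seed) {
  if (folds < 2) stop("folds must be >= 2")
  if (folds > min(table(y))) stop("folds exceeds the smallest class count")
  assignment <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- sample(idx)
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}
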