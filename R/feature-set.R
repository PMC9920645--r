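#' Construct a labeled feature set
#'
#' Bundles an observations-by-features matrix with integer class labels in
#' `1..m`. This is the container every classifier and fitness function in the
#' package consumes.
#'
#' @param X Numeric matrix, one row per observation, one column per feature.
#'   No missing values allowed.
#' @param y Integer class labels, one per row of `X`, taking values in
#'   `1..m` with every class represented at least once and `m >= 2`.
#' @param class_names Optional character vector of length `m` naming the
#'   classes.
#' @return An object of class `labeled_feature_set`: a list with elements
#'   `X`, `y`, `n_classes` and `class_names`.
#' @export
labeled_feature_set <- function(X, y, class_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("X must not contain missing values")
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(y)) stop("y must not contain missing values")
  m <- max(y)
  if (any(y < 1L)) stop("labels must be integers in 1..m")
  if (m < 2L) stop("at least two classes are required")
  if (length(unique(y)) != m) stop("every class in 1..m must have >= 1 observation")
  if (!is.null(class_names)) {
    class_names <- as.character(class_names)
    if (length(class_names) != m) stop("class_names must have one entry per class")
  }
  structure(
    list(X = X, y = y, n_classes = m, class_names = class_names),
    class = "labeled_feature_set"
  )
}

#' @export
print.labeled_feature_set <- function(x, ...) {
  cat(sprintf(
    "<labeled_feature_set> %d observations x %d features, %d classes\n",
    nrow(x$X), ncol(x$X), x$n_classes
  ))
  invisible(x)
}

#' Subset the rows of a labeled feature set
#'
#' @param data A `labeled_feature_set`.
#' @param idx Row indices to keep. All classes must survive the subset.
#' @return A `labeled_feature_set` restricted to `idx`.
#' @export
subset_rows <- function(data, idx) {
  stopifnot(inherits(data, "labeled_feature_set"))
  labeled_feature_set(data$X[idx, , drop = FALSE], data$y[idx], data$class_names)
}

#' Read a feature matrix CSV
#'
#' Expects a header row, one feature column per feature and a column named
#' `label` holding integer class labels.
#'
#' @param path Path to the CSV file.
#' @return A `labeled_feature_set`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature CSV must contain a 'label' column")
  y <- df[["label"]]
  X <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  labeled_feature_set(X, y)
}

#' Write a feature matrix CSV
#'
#' @param data A `labeled_feature_set`.
#' @param path Output path; the label column is written as `label`.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(data, path) {
  stopifnot(inherits(data, "labeled_feature_set"))
  df <- as.data.frame(data$X)
  df$label <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# One-hot {0,1} target matrix (N x m) from integer labels.
one_hot <- function(y, m) {
  T <- matrix(0, nrow = length(y), ncol = m)
  T[cbind(seq_along(y), y)] <- 1
  T
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
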