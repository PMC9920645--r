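#' ELM evaluation configuration
#'
#' Settings for the ELM used as evaluation classifier inside the wrapper and
#' the weight-pruning search. The cross-validation fold assignment is frozen
#' from `seed`, so every fitness value is a deterministic function of the
#' candidate mask.
#'
#' @param n_hidden Hidden-layer size `L`.
#' @param seed Seed for the random input layer (folds use `seed + 1`).
#' @param activation Activation identifier.
#' @return A list of class `elm_config`.
#' @export
elm_config <- function(n_hidden, seed, activation = "sigmoid") {
  structure(list(n_hidden = as.integer(n_hidden), seed = as.integer(seed),
                 activation = activation),
            class = "elm_config")
}

# Mean stratified k-fold validation accuracy of a beta solved on each
# training fold from a precomputed full H (columns of H are hidden nodes).
cv_accuracy_from_H <- function(H, y, n_classes, fold_id) {
  T <- one_hot(y, n_classes)
  accs <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    beta <- pinv_solve(H[tr, , drop = FALSE], T[tr, , drop = FALSE])
    pred <- decode_scores(H[!tr, , drop = FALSE] %*% beta)
    mean(pred == y[!tr])
  }, numeric(1))
  mean(accs)
}

#' Wrapper fitness of a feature mask
#'
#' Mean stratified k-fold validation accuracy of an ELM trained on the
#' masked columns only. The all-zero mask scores 0 without training. The
#' fitness ignores the contents of unselected columns entirely.
#'
#' @param mask 0/1 vector over the features (1 = retained).
#' @param data A [labeled_feature_set()].
#' @param elm_cfg An [elm_config()].
#' @param folds Number of CV folds, `>= 2`.
#' @return Scalar fitness in `[0, 1]`.
#' @export
wrapper_fitness <- function(mask, data, elm_cfg, folds = 5) {
  stopifnot(inherits(data, "labeled_feature_set"))
  if (folds < 2) stop("folds must be >= 2")
  sel <- which(mask == 1)
  if (!length(sel)) return(0)
  fold_id <- kfold_stratified(data$y, folds, elm_cfg$seed + 1L)
  layer <- init_random_layer(length(sel), elm_cfg$n_hidden, elm_cfg$seed)
  H <- hidden_output(data$X[, sel, drop = FALSE], layer$W, layer$b,
                     elm_cfg$activation)
  cv_accuracy_from_H(H, data$y, data$n_classes, fold_id)
}

#' Wrapper feature selection (KTGELM)
#'
#' Runs the k-tournament binary grasshopper optimizer over feature masks
#' with [wrapper_fitness()] as objective. Exact fitness ties are broken
#' toward fewer selected features. With a single feature the only valid
#' mask is returned without search.
#'
#' @param data A [labeled_feature_set()] with `n >= 1` features.
#' @param goa A [goa_params()] object.
#' @param elm_cfg An [elm_config()].
#' @param folds CV folds for the fitness.
#' @param variant Optimizer variant, see [goa_optimize()].
#' @return List of class `feature_selection`: `mask` (0/1 vector),
#'   `selected` (indices), `fitness`, `history`.
#' @export
select_features <- function(data, goa, elm_cfg, folds = 5,
                            variant = "ktgoa") {
  n <- ncol(data$X)
  if (n == 1L) {
    return(structure(list(mask = 1L, selected = 1L,
                          fitness = wrapper_fitness(1L, data, elm_cfg, folds),
                          history = NULL),
                     class = "feature_selection"))
  }
  res <- goa_optimize(
    function(bits) wrapper_fitness(bits, data, elm_cfg, folds),
    D = n, params = goa, variant = variant, tie_break = "sparser"
  )
  structure(
    list(mask = res$best_position, selected = which(res$best_position == 1),
         fitness = res$best_fitness, history = res$history),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d features selected, CV fitness %.4f\n",
              length(x$selected), x$fitness))
  cat("mask:", paste(x$mask, collapse = ""), "\n")
  invisible(x)
}

#' Write a feature-selection result as JSON
#'
#' @param fs A `feature_selection` object.
#' @param path JSON output path.
#' @param history_csv Optional path; if given, the optimizer history is
#'   written there and referenced from the JSON.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(fs, path, history_csv = NULL) {
  if (!is.null(history_csv) && !is.null(fs$history))
    write_trace_csv(fs$history, history_csv)
  jsonlite::write_json(
    list(selected_indices = fs$selected, fitness = fs$fitness,
         mask = paste(fs$mask, collapse = ""),
         history_csv_path = history_csv),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
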