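#' Apply a binary mask to the input-weight matrix
#'
#' Elementwise product: masked-out weights become exactly zero.
#'
#' @param W Input-weight matrix (`n x L`).
#' @param mask 0/1 matrix of the same shape.
#' @return The masked weight matrix.
#' @export
apply_weight_mask <- function(W, mask) {
  mask <- as.matrix(mask)
  if (!all(dim(W) == dim(mask))) stop("W and mask must have equal shapes")
  W * mask
}

#' Derive node- and feature-level pruning from a weight mask
#'
#' A hidden node survives if its column keeps at least one weight; a feature
#' survives if at least one of its weights (its row) is kept. A feature is
#' thus only eliminated when every connection it feeds is eliminated.
#'
#' @param mask 0/1 matrix, rows = features, columns = hidden nodes.
#' @return List with integer vectors `active_nodes` and `active_features`.
#' @export
derive_pruning <- function(mask) {
  mask <- as.matrix(mask)
  list(
    active_nodes = which(colSums(mask) > 0),
    active_features = which(rowSums(mask) > 0)
  )
}

# Hidden output of the masked network on the active nodes only: dead nodes
# (all-zero columns) are dropped so their biases never enter H.
masked_hidden_output <- function(X, W, b, mask, activation, active_nodes) {
  Wm <- apply_weight_mask(W, mask)
  hidden_output(X, Wm[, active_nodes, drop = FALSE], b[active_nodes], activation)
}

#' Fitness of a weight mask
#'
#' Mean stratified k-fold validation accuracy of the ELM whose input weights
#' are `W * mask`, using only the surviving hidden nodes (dead nodes'
#' biases are excluded) and refitting the output weights on each training
#' fold. `W` and `b` are generated once before the search and stay fixed.
#' The all-zero mask scores 0.
#'
#' @param mask 0/1 matrix `n x L` (or a vector of length `n * L`,
#'   column-major).
#' @param data A [labeled_feature_set()].
#' @param W,b Fixed random input layer from [init_random_layer()].
#' @param elm_cfg An [elm_config()] (activation + fold seed).
#' @param folds Number of CV folds.
#' @return Scalar fitness in `[0, 1]`.
#' @export
masked_fitness <- function(mask, data, W, b, elm_cfg, folds = 5) {
  if (!is.matrix(mask)) mask <- matrix(mask, nrow = nrow(W), ncol = ncol(W))
  pr <- derive_pruning(mask)
  if (!length(pr$active_nodes)) return(0)
  fold_id <- kfold_stratified(data$y, folds, elm_cfg$seed + 1L)
  H <- masked_hidden_output(data$X, W, b, mask, elm_cfg$activation, pr$active_nodes)
  cv_accuracy_from_H(H, data$y, data$n_classes, fold_id)
}

#' Train a k-tournament grasshopper extreme learner
#'
#' The random input layer is drawn once; the k-tournament binary grasshopper
#' optimizer then searches the `n * L` weight-mask bits maximizing
#' [masked_fitness()]. The winning mask is compacted (dead nodes dropped,
#' masked weights zeroed) and the output weights are refit once on the full
#' training data. Because the all-ones mask is agent 1 of the initial
#' population, the returned fitness is never below the unpruned ELM's CV
#' fitness, and the winner always keeps at least one node.
#'
#' At paper scale (`48 x 3000 = 144000` bits) the search space is enormous
#' and runs need patience; tests and examples use small `L`.
#'
#' @param data A [labeled_feature_set()].
#' @param n_hidden Initial hidden-layer size `L`.
#' @param goa A [goa_params()] object (its `seed` drives the search).
#' @param elm_cfg An [elm_config()]; its `n_hidden` is overridden by
#'   `n_hidden`.
#' @param folds CV folds inside the fitness.
#' @param variant Optimizer variant, see [goa_optimize()].
#' @return An object of class `ktgel_model`: the compact `W`, `b`, `beta`
#'   over active nodes, `mask`, `active_nodes`, `active_features`,
#'   `fitness` (best CV fitness) and `history`.
#' @export
train_ktgel <- function(data, n_hidden, goa, elm_cfg, folds = 5,
                        variant = "ktgoa") {
  stopifnot(inherits(data, "labeled_feature_set"))
  n <- ncol(data$X)
  layer <- init_random_layer(n, n_hidden, elm_cfg$seed)
  res <- goa_optimize(
    function(bits) masked_fitness(bits, data, layer$W, layer$b, elm_cfg, folds),
    D = n * n_hidden, params = goa, variant = variant
  )
  mask <- matrix(res$best_position, nrow = n, ncol = n_hidden)
  pr <- derive_pruning(mask)
  # final refit of beta on the full training split with the winning mask
  H <- masked_hidden_output(data$X, layer$W, layer$b, mask,
                            elm_cfg$activation, pr$active_nodes)
  beta <- pinv_solve(H, one_hot(data$y, data$n_classes))
  Wm <- apply_weight_mask(layer$W, mask)
  structure(
    list(
      W = Wm[, pr$active_nodes, drop = FALSE],
      b = layer$b[pr$active_nodes],
      beta = beta,
      activation = elm_cfg$activation,
      mask = mask,
      active_nodes = pr$active_nodes,
      active_features = pr$active_features,
      n_features = n,
      n_hidden_initial = as.integer(n_hidden),
      n_classes = data$n_classes,
      class_names = data$class_names,
      fitness = res$best_fitness,
      history = res$history,
      seed = elm_cfg$seed
    ),
    class = "ktgel_model"
  )
}

#' Predict with a pruned model
#'
#' Consumes full-width feature rows (the original `n` columns); eliminated
#' features are ignored internally because their surviving weights are all
#' zero. Identical to predicting with the non-compacted masked model.
#'
#' @param object A `ktgel_model`.
#' @param X Matrix with the original `n_features` columns.
#' @param ... Unused.
#' @return Integer vector of predicted labels.
#' @export
predict.ktgel_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) stop("X has the wrong number of columns")
  H <- hidden_output(X, object$W, object$b, object$activation)
  decode_scores(H %*% object$beta)
}

#' @export
print.ktgel_model <- function(x, ...) {
  cat(sprintf(
    "<ktgel_model> %d/%d features, %d/%d hidden nodes kept | CV fitness %.4f\n",
    length(x$active_features), x$n_features,
    length(x$active_nodes), x$n_hidden_initial, x$fitness
  ))
  invisible(x)
}
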