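#' Random hidden-layer initialization
#'
#' Draws the input-weight matrix `W` (`n_features x n_hidden`) and bias vector
#' `b` (length `n_hidden`) i.i.d. uniform on `[-1, 1]`, reproducibly from
#' `seed`. These weights are never trained: in an extreme learning machine
#' only the output layer is solved.
#'
#' @param n_features Number of input features, `>= 1`.
#' @param n_hidden Number of hidden nodes, `>= 1`.
#' @param seed Integer seed; identical seed and shapes give bit-identical
#'   draws.
#' @return List with elements `W` and `b`.
#' @export
init_random_layer <- function(n_features, n_hidden, seed) {
  if (length(n_features) != 1L || n_features < 1) stop("n_features must be >= 1")
  if (length(n_hidden) != 1L || n_hidden < 1) stop("n_hidden must be >= 1")
  with_seed(seed, {
    W <- matrix(stats::runif(n_features * n_hidden, -1, 1),
                nrow = n_features, ncol = n_hidden)
    b <- stats::runif(n_hidden, -1, 1)
    list(W = W, b = b)
  })
}

# Named activation functions g applied entrywise to x %*% W + b.
activation_fun <- function(activation) {
  switch(activation,
    sigmoid = function(z) 1 / (1 + exp(-z)),
    tanh    = base::tanh,
    radbas  = function(z) exp(-z^2),
    stop(sprintf("unknown activation '%s'", activation))
  )
}

#' Hidden-layer output matrix
#'
#' Computes `H[i, j] = g(x_i . w_j + b_j)` for every observation `i` and
#' hidden node `j`.
#'
#' @param X Numeric matrix of observations (`N x n`).
#' @param W Input-weight matrix (`n x L`).
#' @param b Bias vector of length `L`.
#' @param activation One of `"sigmoid"` (default), `"tanh"`, `"radbas"`.
#' @return The `N x L` hidden-layer output matrix `H`.
#' @export
hidden_output <- function(X, W, b, activation = "sigmoid") {
  X <- as.matrix(X)
  if (ncol(X) != nrow(W)) stop("ncol(X) must equal nrow(W)")
  if (length(b) != ncol(W)) stop("length(b) must equal ncol(W)")
  g <- activation_fun(activation)
  Z <- X %*% W
  Z <- sweep(Z, 2L, b, "+")
  g(Z)
}

# Minimum-norm least-squares solve beta = pinv(H) %*% T via SVD with a
# singular-value cutoff of rtol * sigma_max. This is the Moore-Penrose
# solution: it minimizes ||H beta - T||_F and, among minimizers, ||beta||_F.
pinv_solve <- function(H, T, rtol = 1e-10) {
  sv <- svd(H)
  keep <- sv$d > rtol * sv$d[1]
  if (!any(keep)) return(matrix(0, nrow = ncol(H), ncol = ncol(T)))
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  V %*% ((crossprod(U, T)) / sv$d[keep])
}

#' Train an extreme learning machine
#'
#' Assigns random input weights and biases, computes the hidden-layer output
#' matrix `H`, and solves the output weights `beta = pinv(H) T` where `pinv`
#' is the Moore-Penrose generalized inverse and `T` the one-hot `{0,1}`
#' target matrix. Training is a single linear-algebra step; no iteration.
#'
#' Features are assumed pre-normalized (see [minmax_fit()]); no scaling is
#' applied here.
#'
#' @param data A [labeled_feature_set()].
#' @param n_hidden Number of hidden nodes `L`.
#' @param seed Seed for the random input layer.
#' @param activation Activation identifier, see [hidden_output()].
#' @return An object of class `elm_model` holding `W`, `b`, `beta`,
#'   `activation`, `seed`, `n_features`, `n_hidden`, `n_classes` and
#'   `class_names`.
#' @export
train_elm <- function(data, n_hidden, seed, activation = "sigmoid") {
  stopifnot(inherits(data, "labeled_feature_set"))
  layer <- init_random_layer(ncol(data$X), n_hidden, seed)
  H <- hidden_output(data$X, layer$W, layer$b, activation)
  T <- one_hot(data$y, data$n_classes)
  beta <- pinv_solve(H, T)
  structure(
    list(
      W = layer$W, b = layer$b, beta = beta, activation = activation,
      seed = as.integer(seed), n_features = ncol(data$X),
      n_hidden = as.integer(n_hidden), n_classes = data$n_classes,
      class_names = data$class_names
    ),
    class = "elm_model"
  )
}

# Argmax decode with ties broken toward the lowest class index.
decode_scores <- function(S) {
  max.col(S, ties.method = "first")
}

#' Predict class labels with a trained ELM
#'
#' Scores are `H beta`; the predicted label is the argmax over classes,
#' ties broken toward the lowest class index.
#'
#' @param object An `elm_model` from [train_elm()].
#' @param X Matrix of observations with `n_features` columns.
#' @param ... Unused.
#' @return Integer vector of predicted labels.
#' @export
predict.elm_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) stop("X has the wrong number of columns")
  H <- hidden_output(X, object$W, object$b, object$activation)
  decode_scores(H %*% object$beta)
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf(
    "<elm_model> %d features -> %d hidden (%s) -> %d classes\n",
    x$n_features, x$n_hidden, x$activation, x$n_classes
  ))
  invisible(x)
}
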