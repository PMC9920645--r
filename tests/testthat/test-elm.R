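test_that("init_random_layer is seed-deterministic, bounded, correctly shaped", {
  a <- init_random_layer(2, 3, seed = 7)
  b <- init_random_layer(2, 3, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, init_random_layer(2, 3, seed = 8)))

  big <- init_random_layer(48, 3000, seed = 1)
  expect_equal(dim(big$W), c(48L, 3000L))
  expect_length(big$b, 3000L)
  expect_true(all(big$W >= -1 & big$W <= 1))
  expect_true(all(big$b >= -1 & big$b <= 1))

  expect_error(init_random_layer(0, 3, 1))
  expect_error(init_random_layer(3, 0, 1))
})

test_that("hidden_output matches hand values and a scalar-loop oracle", {
  # zero weights and biases: sigmoid(0) = 0.5 everywhere
  H0 <- hidden_output(matrix(rnorm(12), 3), matrix(0, 4, 5), rep(0, 5))
  expect_equal(H0, matrix(0.5, 3, 5))

  # one sample, one node: argument 1*2 + 0*1 - 2 = 0
  H1 <- hidden_output(matrix(c(1, 0), 1), matrix(c(2, 1), 2, 1), -2)
  expect_equal(H1, matrix(0.5))

  # brute-force scalar recomputation
  set.seed(42)
  X <- matrix(rnorm(20), 5, 4)
  W <- matrix(rnorm(24), 4, 6)
  b <- rnorm(6)
  for (act in c("sigmoid", "tanh", "radbas")) {
    H <- hidden_output(X, W, b, act)
    g <- switch(act, sigmoid = function(z) 1 / (1 + exp(-z)),
                tanh = tanh, radbas = function(z) exp(-z^2))
    for (i in 1:5) for (j in 1:6) {
      z <- sum(X[i, ] * W[, j]) + b[j]
      expect_equal(H[i, j], g(z), tolerance = 1e-12)
    }
  }

  expect_error(hidden_output(matrix(0, 2, 3), matrix(0, 4, 2), c(0, 0)))
  expect_error(hidden_output(matrix(0, 2, 3), matrix(0, 3, 2), c(0, 0),
                             activation = "relu"))
})

test_that("train_elm interpolates exactly when N <= L", {
  set.seed(3)
  X <- matrix(rnorm(25 * 4), 25, 4)
  d <- labeled_feature_set(X, rep(1:5, 5))
  m <- train_elm(d, 40, seed = 10)
  H <- hidden_output(X, m$W, m$b)
  T <- matrix(0, 25, 5); T[cbind(1:25, d$y)] <- 1
  # independent solve: with full row rank the underdetermined system has the
  # closed-form exact solution t(H) (H t(H))^-1 T
  beta0 <- t(H) %*% solve(tcrossprod(H), T)
  expect_lt(norm(H %*% beta0 - T, "F"), 1e-6)
  expect_lt(norm(H %*% m$beta - T, "F"), 1e-6)
  expect_identical(predict(m, X), d$y)
})

test_that("train_elm separates Gaussian blobs as well as a centroid oracle", {
  d <- make_blobs(100, rbind(c(-2, -2), c(2, 2)), sd = 1, seed = 5)
  sp <- stratified_holdout(d$y, 0.25, seed = 9)
  train <- subset_rows(d, sp$train_idx)
  m <- train_elm(train, 50, seed = 4)
  acc <- mean(predict(m, d$X[sp$test_idx, ]) == d$y[sp$test_idx])
  expect_gte(acc, 0.95)
  expect_gte(nearest_centroid_acc(train, d$X[sp$test_idx, ], d$y[sp$test_idx]),
             0.95)
})

test_that("beta solves the normal equations when H'H is invertible", {
  set.seed(8)
  X <- matrix(rnorm(200 * 6), 200, 6)
  d <- labeled_feature_set(X, sample(1:3, 200, replace = TRUE))
  m <- train_elm(d, 12, seed = 2)
  H <- hidden_output(X, m$W, m$b)
  T <- matrix(0, 200, 3); T[cbind(1:200, d$y)] <- 1
  beta_ne <- solve(crossprod(H), crossprod(H, T))
  expect_equal(m$beta, beta_ne, tolerance = 1e-8)
})

test_that("predict decodes argmax with lowest-index tie-break", {
  m <- structure(
    list(W = matrix(0, 2, 3), b = rep(0, 3), beta = matrix(0, 3, 4),
         activation = "sigmoid", seed = 1L, n_features = 2L, n_hidden = 3L,
         n_classes = 4L, class_names = NULL),
    class = "elm_model"
  )
  # beta = 0: every score row identical -> all class 1
  expect_identical(predict(m, matrix(rnorm(10), 5, 2)), rep(1L, 5))

  # direct argmax on a score row
  m$beta <- matrix(0, 3, 3)
  m$beta[1, ] <- c(0.1, 0.9, 0.3) / 0.5   # H is all 0.5 under W=0,b=0
  m$n_classes <- 3L
  expect_identical(predict(m, matrix(0, 1, 2)), 2L)

  expect_error(predict(m, matrix(0, 1, 5)))
})

test_that("degenerate single-class data is rejected", {
  expect_error(labeled_feature_set(matrix(rnorm(10), 5), rep(1, 5)))
})

test_that("exact interpolation holds across seeds and pipeline is reproducible", {
  for (s in 1:10) {
    set.seed(100 + s)
    X <- matrix(rnorm(15 * 3), 15, 3)
    d <- labeled_feature_set(X, rep(1:3, 5))
    m <- train_elm(d, 20, seed = s)
    H <- hidden_output(X, m$W, m$b)
    T <- matrix(0, 15, 3); T[cbind(1:15, d$y)] <- 1
    expect_lt(norm(H %*% m$beta - T, "F"), 1e-6)
  }

  d <- make_blobs(30, rbind(c(0, 0), c(1, 1)), seed = 2)
  m1 <- train_elm(d, 10, seed = 77)
  m2 <- train_elm(d, 10, seed = 77)
  expect_identical(m1, m2)
  expect_identical(predict(m1, d$X), predict(m2, d$X))
})

test_that("label-permuted data scores at chance level", {
  set.seed(21)
  X <- matrix(rnorm(500 * 5), 500, 5)
  y <- rep(1:4, length.out = 500)
  d <- labeled_feature_set(X, sample(y))   # labels carry no information
  sp <- stratified_holdout(d$y, 0.25, seed = 3)
  m <- train_elm(subset_rows(d, sp$train_idx), 30, seed = 6)
  acc <- mean(predict(m, d$X[sp$test_idx, ]) == d$y[sp$test_idx])
  expect_lt(abs(acc - 0.25), 0.1)
})
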