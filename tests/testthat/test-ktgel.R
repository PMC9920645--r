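# Small fixed instance used across several blocks: 2 features, 3 hidden
# nodes, 40 samples -> the 2^6 = 64 possible weight masks are enumerable.
tiny_instance <- function() {
  d <- make_blobs(20, rbind(c(-1, 0), c(1.2, 0.4)), sd = 0.8, seed = 18)
  layer <- init_random_layer(2, 3, seed = 19)
  list(data = d, W = layer$W, b = layer$b, cfg = elm_config(3, seed = 19))
}

test_that("weight-mask algebra behaves elementwise", {
  set.seed(20)
  W <- matrix(rnorm(12), 3, 4)
  expect_identical(apply_weight_mask(W, matrix(1, 3, 4)), W)
  expect_equal(apply_weight_mask(W, matrix(0, 3, 4)), matrix(0, 3, 4))
  m1 <- matrix(1, 3, 4); m1[2, 3] <- 0
  expect_equal(sum(apply_weight_mask(W, m1) != W), 1L)
  expect_error(apply_weight_mask(W, matrix(1, 4, 3)))
})

test_that("pruning derivation matches a brute-force row/column scan", {
  mask <- matrix(1L, 4, 5); mask[, 3] <- 0L
  expect_equal(derive_pruning(mask)$active_nodes, c(1L, 2L, 4L, 5L))
  mask2 <- matrix(1L, 4, 5); mask2[2, ] <- 0L
  pr2 <- derive_pruning(mask2)
  expect_equal(pr2$active_features, c(1L, 3L, 4L))
  expect_equal(pr2$active_nodes, 1:5)

  set.seed(21)
  for (i in 1:200) {
    m <- random_mask(sample(2:6, 1), sample(2:8, 1), p = 0.3)
    pr <- derive_pruning(m)
    # column/row scan oracle
    nodes <- integer(0); feats <- integer(0)
    for (j in seq_len(ncol(m))) if (any(m[, j] == 1)) nodes <- c(nodes, j)
    for (r in seq_len(nrow(m))) if (any(m[r, ] == 1)) feats <- c(feats, r)
    expect_identical(pr$active_nodes, nodes)
    expect_identical(pr$active_features, feats)
    expect_equal(length(pr$active_nodes), ncol(m) - sum(colSums(m) == 0))
  }
})

test_that("masked fitness reduces to the plain ELM on the all-ones mask", {
  ti <- tiny_instance()
  fit_all <- masked_fitness(matrix(1L, 2, 3), ti$data, ti$W, ti$b, ti$cfg, 5)
  fold_id <- kfold_stratified(ti$data$y, 5, ti$cfg$seed + 1L)
  expect_identical(fit_all, cv_accuracy_oracle(ti$data, fold_id, 3, ti$cfg$seed))
  expect_identical(masked_fitness(matrix(0L, 2, 3), ti$data, ti$W, ti$b, ti$cfg), 0)
})

test_that("masked-out weights are dead: their values cannot matter", {
  ti <- tiny_instance()
  mask <- matrix(c(1L, 0L, 1L, 1L, 0L, 1L), 2, 3)
  f1 <- masked_fitness(mask, ti$data, ti$W, ti$b, ti$cfg)
  W2 <- ti$W; W2[mask == 0] <- 1e6
  f2 <- masked_fitness(mask, ti$data, W2, ti$b, ti$cfg)
  expect_identical(f1, f2)
})

test_that("masked fitness equals a from-scratch reduced-architecture ELM for all 64 masks", {
  ti <- tiny_instance()
  fold_id <- kfold_stratified(ti$data$y, 5, ti$cfg$seed + 1L)
  T_full <- diag(2)[ti$data$y, ]
  oracle <- function(mask) {
    active <- which(colSums(mask) > 0)
    if (!length(active)) return(0)
    Wred <- (ti$W * mask)[, active, drop = FALSE]
    bred <- ti$b[active]
    accs <- vapply(1:5, function(f) {
      tr <- fold_id != f
      H <- hidden_output(ti$data$X[tr, , drop = FALSE], Wred, bred)
      beta <- qr.coef(qr(H, LAPACK = TRUE), T_full[tr, , drop = FALSE])
      Hv <- hidden_output(ti$data$X[!tr, , drop = FALSE], Wred, bred)
      mean(max.col(Hv %*% beta, ties.method = "first") == ti$data$y[!tr])
    }, numeric(1))
    mean(accs)
  }
  for (code in 0:63) {
    mask <- matrix(as.integer(intToBits(code)[1:6]), 2, 3)
    expect_equal(masked_fitness(mask, ti$data, ti$W, ti$b, ti$cfg),
                 oracle(mask), tolerance = 1e-12)
  }
})

test_that("train_ktgel at zero budget keeps the elitism floor and all-ones parity", {
  ti <- tiny_instance()
  kt <- train_ktgel(ti$data, 3, goa_params(4, 0, k = 2, seed = 22), ti$cfg)
  expect_gte(kt$fitness,
             masked_fitness(matrix(1L, 2, 3), ti$data, ti$W, ti$b, ti$cfg))
  expect_gte(length(kt$active_nodes), 1L)
  expect_true(all(diff(kt$history$best_fitness) >= 0))

  # when the winning mask is all-ones the model IS the plain ELM
  if (all(kt$mask == 1L)) {
    elm <- train_elm(ti$data, 3, ti$cfg$seed)
    expect_identical(predict(kt, ti$data$X), predict(elm, ti$data$X))
    expect_equal(kt$beta, elm$beta)
  }
})

test_that("an all-ones-mask model predicts bit-identically to the plain ELM", {
  d <- make_blobs(25, rbind(c(0, 0, 1), c(2, 1, 0), c(-1, 2, 2)), seed = 23)
  L <- 12
  layer <- init_random_layer(3, L, seed = 24)
  mask <- matrix(1L, 3, L)
  H <- hidden_output(d$X, layer$W, layer$b)
  beta <- ktgel:::pinv_solve(H, diag(3)[d$y, ])
  model <- structure(
    list(W = layer$W, b = layer$b, beta = beta, activation = "sigmoid",
         mask = mask, active_nodes = 1:L, active_features = 1:3,
         n_features = 3L, n_hidden_initial = L, n_classes = 3L,
         class_names = NULL, fitness = NA_real_, history = NULL, seed = 24L),
    class = "ktgel_model"
  )
  elm <- train_elm(d, L, seed = 24)
  set.seed(25)
  Xnew <- matrix(rnorm(600), 200, 3)
  expect_identical(predict(model, Xnew), predict(elm, Xnew))
})

test_that("eliminated features are inert and compaction preserves predictions", {
  set.seed(26)
  n <- 4; L <- 6
  d <- make_blobs(20, rbind(c(0, 0, 0, 0), c(2, 2, 0, 0), c(0, 2, 2, 0)),
                  sd = 0.7, seed = 27)
  layer <- init_random_layer(n, L, seed = 28)
  mask <- random_mask(n, L, p = 0.5)
  mask[4, ] <- 0L   # eliminate feature 4
  mask[, 5] <- 0L   # kill node 5
  pr <- derive_pruning(mask)
  Wm <- apply_weight_mask(layer$W, mask)

  Hc <- hidden_output(d$X, Wm[, pr$active_nodes, drop = FALSE],
                      layer$b[pr$active_nodes])
  beta <- ktgel:::pinv_solve(Hc, diag(3)[d$y, ])
  compact <- structure(
    list(W = Wm[, pr$active_nodes, drop = FALSE], b = layer$b[pr$active_nodes],
         beta = beta, activation = "sigmoid", mask = mask,
         active_nodes = pr$active_nodes, active_features = pr$active_features,
         n_features = n, n_hidden_initial = L, n_classes = 3L,
         class_names = NULL, fitness = NA_real_, history = NULL, seed = 28L),
    class = "ktgel_model"
  )

  Xnew <- matrix(rnorm(1000 * n), 1000, n)
  p_compact <- predict(compact, Xnew)

  # permuting the eliminated feature's column cannot change predictions
  Xperm <- Xnew; Xperm[, 4] <- sample(Xperm[, 4])
  expect_identical(predict(compact, Xperm), p_compact)

  # non-compacted masked model: all L nodes, dead column zeroed in H
  Hfull <- hidden_output(Xnew, Wm, layer$b)
  Hfull[, setdiff(1:L, pr$active_nodes)] <- 0
  Htr <- hidden_output(d$X, Wm, layer$b)
  Htr[, setdiff(1:L, pr$active_nodes)] <- 0
  beta_full <- ktgel:::pinv_solve(Htr, diag(3)[d$y, ])
  p_full <- max.col(Hfull %*% beta_full, ties.method = "first")
  expect_identical(p_compact, p_full)
})

test_that("the search recovers the exhaustive optimum on the tiny instance", {
  ti <- tiny_instance()
  best_exhaustive <- max(vapply(0:63, function(code) {
    masked_fitness(matrix(as.integer(intToBits(code)[1:6]), 2, 3),
                   ti$data, ti$W, ti$b, ti$cfg)
  }, numeric(1)))
  hits <- 0L
  for (s in 1:5) {
    kt <- train_ktgel(ti$data, 3, goa_params(20, 60, k = 3, seed = 400 + s),
                      ti$cfg)
    expect_lte(kt$fitness, best_exhaustive)
    if (kt$fitness == best_exhaustive) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
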