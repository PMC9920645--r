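# Shared fixture builders. Everything is generated in code under fixed seeds.

# Gaussian blob classification set: one spherical cluster per class.
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  centers <- as.matrix(centers)
  m <- nrow(centers)
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(m), function(k) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)
  }))
  labeled_feature_set(X, rep(seq_len(m), each = n_per))
}

# Nearest-centroid classifier: the independent separability oracle.
nearest_centroid_acc <- function(train, test_X, test_y) {
  ctr <- vapply(seq_len(train$n_classes), function(k)
    colMeans(train$X[train$y == k, , drop = FALSE]), numeric(ncol(train$X)))
  pred <- apply(test_X, 1L, function(x) which.min(colSums((ctr - x)^2)))
  mean(pred == test_y)
}

# Independent CV oracle: per fold, train a fresh ELM on the training rows
# and score the validation rows. Uses only the public ELM surface.
cv_accuracy_oracle <- function(data, fold_id, n_hidden, seed,
                               activation = "sigmoid") {
  accs <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    model <- train_elm(subset_rows(data, which(tr)), n_hidden, seed, activation)
    mean(predict(model, data$X[!tr, , drop = FALSE]) == data$y[!tr])
  }, numeric(1))
  mean(accs)
}

# Small normalized synthetic FMG feature set, split into train/test parts.
fmg_split <- function(cfg, test_frac = 0.2, split_seed = 11) {
  fs <- generate_fmg_features(cfg)
  sp <- stratified_holdout(fs$y, test_frac, split_seed)
  norm <- minmax_fit(fs$X[sp$train_idx, , drop = FALSE])
  Xn <- minmax_apply(fs$X, norm)
  list(
    train = labeled_feature_set(Xn[sp$train_idx, , drop = FALSE],
                                fs$y[sp$train_idx], fs$class_names),
    test_X = Xn[sp$test_idx, , drop = FALSE],
    test_y = fs$y[sp$test_idx],
    n_classes = fs$n_classes
  )
}

# Random 0/1 mask matrix.
random_mask <- function(n, L, p = 0.5) {
  matrix(rbinom(n * L, 1L, p), n, L)
}
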