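fast_grid <- data.frame(nrounds = 50L, max_depth = 3L, eta = 0.3)

test_that("the boosted base model learns a smooth descriptor function", {
  set.seed(2)
  X <- matrix(rnorm(60 * 5), 60, 5,
              dimnames = list(NULL, paste0("d", 1:5)))
  y <- 2 * X[, 1] - X[, 2] + rnorm(60, 0, 0.05)
  fit <- train_base_model(X, y, grid = fast_grid, seed = 7)
  pred <- predict(fit$booster, xgboost::xgb.DMatrix(X))
  expect_gt(q_squared(y, pred), 0.9)
})

test_that("a degenerate constant target is rejected", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(train_base_model(X, rep(5, 20), grid = fast_grid, seed = 1),
               "degenerate")
})

test_that("training is deterministic for a fixed seed", {
  set.seed(3)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- X[, 1] + rnorm(50, 0, 0.1)
  f1 <- train_base_model(X, y, grid = fast_grid, seed = 11)
  f2 <- train_base_model(X, y, grid = fast_grid, seed = 11)
  expect_equal(f1$n_trees, f2$n_trees)
  expect_identical(predict(f1$booster, xgboost::xgb.DMatrix(X)),
                   predict(f2$booster, xgboost::xgb.DMatrix(X)))
})

test_that("leaf embedding reconstructs the ensemble prediction", {
  set.seed(4)
  X <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(80, 0, 0.1)
  fit <- train_base_model(X, y, grid = fast_grid, seed = 2)
  Xq <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("d", 1:6)))
  emb <- leaf_embed(fit, Xq)
  expect_equal(dim(emb), c(10, fit$n_trees))
  raw <- predict(fit$booster, xgboost::xgb.DMatrix(Xq))
  expect_equal(rowSums(emb) + fit$base_score, raw, tolerance = 1e-4)
})

test_that("a single-tree ensemble embeds into one dimension", {
  set.seed(5)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- X[, 1] + rnorm(30, 0, 0.1)
  fit <- train_base_model(X, y,
                          grid = data.frame(nrounds = 1L, max_depth = 3L,
                                            eta = 0.3), seed = 1)
  expect_equal(fit$n_trees, 1)
  expect_equal(ncol(leaf_embed(fit, X)), 1)
  # identical feature vectors land in identical leaves
  emb <- leaf_embed(fit, X[c(1, 1), , drop = FALSE])
  expect_identical(emb[1, ], emb[2, ])
})

test_that("the AD grid is the 20-percentile kth-neighbour distance ladder", {
  set.seed(6)
  emb <- matrix(rnorm(40 * 7), 40, 7)
  grid <- build_ad_grid(emb, k = 3)
  expect_length(grid$thresholds, 20)
  expect_true(all(diff(grid$thresholds) >= 0))
  expect_true(all(grid$thresholds >= 0))
  expect_equal(grid$percentiles, seq(5, 100, 5))
})

test_that("AD grid matches the hand-worked collinear example", {
  emb <- matrix(c(0, 1, 2, 3, 4), ncol = 1)
  grid <- build_ad_grid(emb, k = 3)
  # max-3NN distances are {3, 2, 2, 2, 3}; the 100th percentile is 3
  expect_equal(sort(grid$max_knn_dist), c(2, 2, 2, 3, 3))
  expect_equal(unname(grid$thresholds[["p100"]]), 3)
  expect_error(build_ad_grid(emb[1:3, , drop = FALSE], k = 3), "k \\+ 1")
})

test_that("degenerate identical training points give an all-zero grid", {
  emb <- matrix(1, 10, 4)
  grid <- build_ad_grid(emb, k = 3)
  expect_true(all(grid$thresholds == 0))
})

test_that("kNN search agrees with the brute-force oracle", {
  set.seed(7)
  for (rep in 1:5) {
    ref <- matrix(rnorm(60 * 5), 60, 5)
    q <- matrix(rnorm(8 * 5), 8, 5)
    fast <- cb2screen:::knn_search(q, ref, k = 3)
    slow <- brute_knn(q, ref, k = 3)
    expect_equal(fast$idx, slow$idx)
    expect_equal(fast$dist, slow$dist, tolerance = 1e-12)
  }
})

test_that("AD-gated prediction averages neighbour experimental pKi", {
  fx <- small_feature_set()
  n <- length(fx$features$ids)
  pki <- seq(5, 9, length.out = n)
  model <- train_qsar_model(fx$features, pki, grid = fast_grid, seed = 9)

  # a query identical to a training compound, with that compound's feature
  # vector tripled in the training set, predicts that compound's pKi exactly
  trip <- subset_features(fx$features, c(1, 1, 1, 2:n))
  trip$ids <- c("q1", "q2", "q3", fx$features$ids[2:n])
  m2 <- train_qsar_model(trip, c(7, 7, 7, pki[2:n]), grid = fast_grid,
                         seed = 9)
  p <- predict(m2, subset_features(fx$features, 1),
               threshold_percentile = 100)
  expect_true(p$in_domain)
  expect_equal(p$pki_pred, 7)

  # threshold 0 puts any query at positive neighbour distance out of domain
  p_far <- predict(model, subset_features(fx$features, 10), threshold = 0)
  expect_gt(p_far$max_neighbor_distance, 0)
  expect_false(p_far$in_domain)
  expect_true(is.na(p_far$pki_pred))

  expect_error(predict(model, fx$features, threshold = -1), "non-negative")
  # diagnostics are always populated, in or out of domain
  pd <- predict(model, fx$features, threshold_percentile = 5)
  expect_true(all(is.finite(pd$max_neighbor_distance)))
  expect_equal(is.na(pd$pki_pred), !pd$in_domain)
  expect_true(all(lengths(pd$neighbor_ids) == 3))
})

test_that("in-domain coverage is non-decreasing in the threshold", {
  fx <- small_feature_set()
  n <- length(fx$features$ids)
  pki <- seq(5, 9, length.out = n)
  idx_train <- seq_len(n) %% 2 == 0
  model <- train_qsar_model(subset_features(fx$features, idx_train),
                            pki[idx_train], grid = fast_grid, seed = 4)
  held <- subset_features(fx$features, !idx_train)
  cov <- vapply(model$ad_grid$percentiles, function(p) {
    mean(predict(model, held, threshold_percentile = p)$in_domain)
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("leave-self-out training queries are in-domain at the loosest threshold", {
  fx <- small_feature_set()
  n <- length(fx$features$ids)
  pki <- seq(5, 9, length.out = n)
  model <- train_qsar_model(fx$features, pki, grid = fast_grid, seed = 9)
  nn <- cb2screen:::knn_search(model$embeddings, model$embeddings, k = 3,
                               exclude_self = TRUE)
  maxd <- nn$dist[, 3]
  expect_gte(mean(maxd <= model$ad_grid$thresholds[["p100"]]), 0.95)
})
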