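# QSAR model: a gradient-boosted tree ensemble is fit to pKi, then each
# training compound is re-represented by the vector of per-tree leaf output
# values ("leaf-value embedding").  Predictions for new compounds are made by
# a k-nearest-neighbour rule in that embedding: the mean experimental pKi of
# the k = 3 nearest training compounds, returned only when all k neighbours
# lie within an applicability-domain distance threshold.  Thresholds are the
# 5th..100th percentiles (step 5) of the training distribution of
# kth-neighbour distances.

#' Default hyperparameter grid for the boosted base model
#'
#' @return A data.frame of grid points over boosting rounds, tree depth and
#'   learning rate.
#' @export
default_hyper_grid <- function() {
  expand.grid(nrounds = c(100L, 300L), max_depth = c(3L, 6L),
              eta = c(0.05, 0.1), KEEP.OUT.ATTRS = FALSE)
}

.xgb_fit <- function(X, y, nrounds, max_depth, eta, seed) {
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = eta,
                  max_depth = max_depth, tree_method = "hist",
                  max_bin = 64, nthread = 1, seed = seed,
                  base_score = mean(y)),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = nrounds, verbose = 0)
}

#' Train the gradient-boosted base model
#'
#' Fits a boosted regression-tree ensemble to pKi, selecting hyperparameters
#' by grid search in an inner k-fold cross-validation (mean squared error),
#' then refits the winning grid point on the full input.  Deterministic for a
#' fixed seed (single-threaded histogram construction).
#'
#' @param X Numeric feature matrix (compounds x features).
#' @param y Numeric pKi vector.
#' @param grid Hyperparameter grid, a data.frame with columns `nrounds`,
#'   `max_depth`, `eta` (default [default_hyper_grid()]).
#' @param inner_folds Folds of the inner model-selection loop (default 5).
#' @param seed Integer seed controlling fold assignment and tree fitting.
#' @return List of class `boosted_ensemble`: the fitted booster, the chosen
#'   grid point, per-tree leaf-value lookup tables, `base_score`, `n_trees`
#'   and the inner-CV error table.
#' @export
train_base_model <- function(X, y, grid = default_hyper_grid(),
                             inner_folds = 5, seed = 1) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= inner_folds)
  if (stats::var(y) == 0) stop("degenerate target: pKi has zero variance")

  set.seed(seed)
  fold <- sample(rep(seq_len(inner_folds), length.out = nrow(X)))
  cv_err <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sse <- 0
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      fit <- .xgb_fit(X[tr, , drop = FALSE], y[tr], grid$nrounds[g],
                      grid$max_depth[g], grid$eta[g], seed)
      pred <- predict(fit, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
      sse <- sse + sum((y[!tr] - pred)^2)
    }
    cv_err[g] <- sse / length(y)
  }
  best <- which.min(cv_err)
  booster <- .xgb_fit(X, y, grid$nrounds[best], grid$max_depth[best],
                      grid$eta[best], seed)

  tt <- xgboost::xgb.model.dt.tree(model = booster)
  leaves <- tt[tt$Feature == "Leaf", c("Tree", "Node", "Gain")]
  n_trees <- max(leaves$Tree) + 1L
  leaf_values <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    lt <- leaves[leaves$Tree == t - 1L, ]
    v <- rep(NA_real_, max(lt$Node) + 1L)
    v[lt$Node + 1L] <- lt$Gain
    leaf_values[[t]] <- v
  }

  structure(list(booster = booster, params = grid[best, , drop = FALSE],
                 leaf_values = leaf_values, base_score = mean(y),
                 n_trees = n_trees,
                 cv_error = cbind(grid, mse = cv_err),
                 feature_names = colnames(X)),
            class = "boosted_ensemble")
}

#' @export
print.boosted_ensemble <- function(x, ...) {
  cat("<boosted_ensemble> ", x$n_trees, " trees (nrounds=",
      x$params$nrounds, ", depth=", x$params$max_depth, ", eta=",
      x$params$eta, ")\n", sep = "")
  invisible(x)
}

#' Leaf-value embedding of compounds
#'
#' Routes each feature vector through every tree of the ensemble and returns
#' the leaf *output value* reached in each tree, so a compound is embedded as
#' a point in an n-trees-dimensional space whose coordinates are in pKi
#' units.  The row sums of the embedding plus the ensemble's base score
#' reproduce the ensemble's raw predictions exactly.
#'
#' @param ensemble A `boosted_ensemble`.
#' @param X Feature matrix in the ensemble's feature space.
#' @return Numeric matrix (compounds x trees).
#' @export
leaf_embed <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "boosted_ensemble"), is.matrix(X))
  li <- predict(ensemble$booster, xgboost::xgb.DMatrix(X), predleaf = TRUE)
  if (is.null(dim(li))) li <- matrix(li, nrow = nrow(X))
  emb <- matrix(NA_real_, nrow(X), ensemble$n_trees)
  for (t in seq_len(ensemble$n_trees))
    emb[, t] <- ensemble$leaf_values[[t]][li[, t] + 1L]
  emb
}

#' k-nearest neighbours by Euclidean distance
#'
#' Exact search; ties at the kth neighbour are broken by row order of the
#' reference matrix (stable), so results are reproducible for a fixed
#' training-set ordering.
#'
#' @param query Numeric matrix of query points.
#' @param ref Numeric matrix of reference points (same column count).
#' @param k Number of neighbours.
#' @param exclude_self If `TRUE`, a reference row identical in index to the
#'   query row is skipped (leave-one-out over the same matrix).
#' @return List with integer matrix `idx` (queries x k) and numeric matrix
#'   `dist`.
#' @keywords internal
knn_search <- function(query, ref, k, exclude_self = FALSE) {
  stopifnot(ncol(query) == ncol(ref), k >= 1,
            nrow(ref) >= k + as.integer(exclude_self))
  nq <- nrow(query)
  idx <- matrix(NA_integer_, nq, k)
  dst <- matrix(NA_real_, nq, k)
  ref_sq <- rowSums(ref^2)
  for (i in seq_len(nq)) {
    d2 <- ref_sq - 2 * as.numeric(ref %*% query[i, ]) + sum(query[i, ]^2)
    d2[d2 < 0] <- 0
    if (exclude_self) d2[i] <- Inf
    ord <- order(d2)[seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- sqrt(d2[ord])
  }
  list(idx = idx, dist = dst)
}

#' Build the applicability-domain threshold grid
#'
#' For every training compound, the distance to its kth-nearest training
#' neighbour (self excluded) is recorded; the grid is the 5th, 10th, ...,
#' 100th percentiles (20 values) of that distance distribution.  A query
#' compound is in-domain at a threshold when all of its k nearest training
#' neighbours lie within that distance.
#'
#' @param embeddings Numeric matrix of training leaf embeddings.
#' @param k Neighbour count (default 3).
#' @return List of class `ad_grid` with `thresholds` (named, length 20),
#'   `percentiles`, `max_knn_dist` (the underlying distribution) and `k`.
#' @export
build_ad_grid <- function(embeddings, k = 3) {
  stopifnot(is.matrix(embeddings))
  if (nrow(embeddings) < k + 1)
    stop("need at least k + 1 training embeddings")
  nn <- knn_search(embeddings, embeddings, k = k, exclude_self = TRUE)
  maxd <- nn$dist[, k]
  pct <- seq(5, 100, by = 5)
  thr <- stats::quantile(maxd, probs = pct / 100, names = FALSE)
  structure(list(thresholds = stats::setNames(thr, paste0("p", pct)),
                 percentiles = pct, max_knn_dist = maxd, k = k),
            class = "ad_grid")
}

#' @export
print.ad_grid <- function(x, ...) {
  cat("<ad_grid> k =", x$k, "|", length(x$thresholds),
      "thresholds from", signif(x$thresholds[1], 4), "to",
      signif(x$thresholds[length(x$thresholds)], 4), "\n")
  invisible(x)
}

#' Train a complete QSAR model with applicability domain
#'
#' Convenience wrapper tying the pieces together: learns the descriptor
#' variance mask on the training compounds, fits the boosted base model with
#' inner-CV grid search, embeds the training set in leaf-value space, and
#' builds the AD threshold grid.  The returned object carries everything
#' needed to predict new compounds, including the training fingerprints used
#' for Tanimoto novelty scoring.
#'
#' @param features A `feature_set` for the training compounds.
#' @param pki Numeric vector of experimental pKi values.
#' @param target Target label stored with the model (e.g. `"CB1"`).
#' @param grid,inner_folds,seed Passed to [train_base_model()].
#' @param k Neighbour count for the AD (default 3).
#' @param min_variance Descriptor variance cutoff (default 0.05).
#' @return List of class `qsar_model`.
#' @export
train_qsar_model <- function(features, pki, target = NA_character_,
                             grid = default_hyper_grid(), inner_folds = 5,
                             seed = 1, k = 3, min_variance = 0.05) {
  stopifnot(inherits(features, "feature_set"),
            nrow(features$descriptors) == length(pki))
  filt <- filter_descriptor_matrix(features$descriptors,
                                   min_variance = min_variance)
  X <- cbind(filt$matrix, features$fingerprints)
  ensemble <- train_base_model(X, pki, grid = grid,
                               inner_folds = inner_folds, seed = seed)
  emb <- leaf_embed(ensemble, X)
  ad <- build_ad_grid(emb, k = k)
  structure(list(ensemble = ensemble, embeddings = emb, ad_grid = ad,
                 train_pki = pki, train_ids = features$ids,
                 train_fingerprints = features$fingerprints,
                 descriptor_mask = filt$keep, k = k, seed = seed,
                 target = target),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("<qsar_model>", if (!is.na(x$target)) x$target, "|",
      length(x$train_pki), "training compounds |", x$ensemble$n_trees,
      "trees | k =", x$k, "\n")
  invisible(x)
}

# Resolve a threshold specification against a model's AD grid.
.resolve_threshold <- function(model, threshold = NULL,
                               threshold_percentile = NULL) {
  if (is.null(threshold)) {
    if (is.null(threshold_percentile)) threshold_percentile <- 100
    i <- match(threshold_percentile, model$ad_grid$percentiles)
    if (is.na(i)) stop("threshold_percentile must be one of 5, 10, ..., 100")
    threshold <- model$ad_grid$thresholds[[i]]
  }
  if (threshold < 0) stop("threshold must be non-negative")
  threshold
}

#' Predict pKi with applicability-domain gating
#'
#' Embeds query compounds in the model's leaf-value space, finds the k
#' nearest training compounds, and predicts the arithmetic mean of their
#' *experimental* pKi values — but only when all k neighbours are within the
#' chosen distance threshold; otherwise the compound is flagged out-of-domain
#' and no value is returned.  Distance diagnostics are always populated.
#'
#' @param object A `qsar_model`.
#' @param features A `feature_set` for the query compounds (featurized with
#'   the same fingerprint parameters as the training set).
#' @param threshold Absolute distance threshold; alternatively give
#'   `threshold_percentile`.
#' @param threshold_percentile One of 5, 10, ..., 100 selecting a grid
#'   threshold (default 100, the most inclusive).
#' @param ... Unused.
#' @return A [tibble::tibble] with columns `id`, `pki_pred` (NA when out of
#'   domain), `in_domain`, `max_neighbor_distance`, `threshold_used` and a
#'   list-column `neighbor_ids` of the k nearest training identifiers.
#' @export
predict.qsar_model <- function(object, features, threshold = NULL,
                               threshold_percentile = NULL, ...) {
  stopifnot(inherits(features, "feature_set"))
  thr <- .resolve_threshold(object, threshold, threshold_percentile)
  X <- assemble_features(features, object$descriptor_mask)
  emb <- leaf_embed(object$ensemble, X)
  nn <- knn_search(emb, object$embeddings, k = object$k)
  maxd <- nn$dist[, object$k]
  in_dom <- maxd <= thr
  pred <- ifelse(in_dom, rowMeans(matrix(object$train_pki[nn$idx],
                                         nrow = nrow(emb))), NA_real_)
  tibble::tibble(
    id = features$ids %||% as.character(seq_len(nrow(X))),
    pki_pred = pred,
    in_domain = in_dom,
    max_neighbor_distance = maxd,
    threshold_used = thr,
    neighbor_ids = lapply(seq_len(nrow(emb)), function(i)
      object$train_ids[nn$idx[i, ]])
  )
}
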