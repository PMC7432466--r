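# Model validation: cross-validated Q2 and its dependence on the
# applicability-domain threshold.  Everything inside a fold (descriptor
# variance mask, hyperparameter selection, leaf embedding, AD grid) is refit
# on that fold's training part only, so no information from a test compound
# reaches its own fold's model.

#' Cross-validated coefficient of determination Q2
#'
#' \eqn{Q^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2},
#' with the mean taken over the evaluated subset.  Equals 1 for perfect
#' predictions and 0 for the subset-mean predictor.
#'
#' @param y_true Observed values (length >= 2, non-constant).
#' @param y_pred Predicted values, same length.
#' @return The Q2 value.
#' @examples
#' q_squared(c(4, 6, 8), c(5, 6, 7))  # 0.75
#' @export
q_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("y_true is constant; Q2 undefined")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Cross-validate a QSAR model over the AD threshold grid
#'
#' Splits the dataset into `folds` random folds (seeded).  For each fold a
#' full model is trained on the remaining compounds — descriptor variance
#' mask, inner-grid-search boosted ensemble, leaf embedding and AD grid all
#' refit — and the held-out compounds are predicted at each of the fold's 20
#' AD thresholds.  Per threshold level, Q2 is computed over the pooled
#' in-domain out-of-sample predictions (NA when fewer than two in-domain
#' compounds or a constant observed subvector makes it undefined), along
#' with the in-domain coverage fraction.
#'
#' @param features A `feature_set` for all compounds.
#' @param pki Numeric vector of experimental pKi values.
#' @param folds Number of outer folds (default 5).
#' @param seed Integer seed for fold assignment and model fitting.
#' @param grid,inner_folds,k,min_variance Passed to [train_qsar_model()].
#' @return List of class `cv_result`: `predictions` (compounds x 20 matrix of
#'   out-of-sample predictions, NA = out of domain), `max_dist`, `fold`
#'   (assignments), `pki`, `summary` (tibble: percentile, mean threshold,
#'   coverage, q2) and `seed`.
#' @export
cross_validate <- function(features, pki, folds = 5, seed = 1,
                           grid = default_hyper_grid(), inner_folds = 5,
                           k = 3, min_variance = 0.05) {
  stopifnot(inherits(features, "feature_set"), length(pki) >= folds)
  n <- length(pki)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  pct <- seq(5, 100, by = 5)
  preds <- matrix(NA_real_, n, length(pct),
                  dimnames = list(features$ids, paste0("p", pct)))
  maxd <- rep(NA_real_, n)
  thr_used <- matrix(NA_real_, folds, length(pct))

  for (f in seq_len(folds)) {
    tr <- fold != f
    tr_feats <- subset_features(features, tr)
    te_feats <- subset_features(features, !tr)
    model <- train_qsar_model(tr_feats, pki[tr], grid = grid,
                              inner_folds = inner_folds,
                              seed = seed + f, k = k,
                              min_variance = min_variance)
    thr_used[f, ] <- model$ad_grid$thresholds
    X <- assemble_features(te_feats, model$descriptor_mask)
    emb <- leaf_embed(model$ensemble, X)
    nn <- knn_search(emb, model$embeddings, k = k)
    d <- nn$dist[, k]
    maxd[!tr] <- d
    knn_pred <- rowMeans(matrix(model$train_pki[nn$idx], nrow = nrow(emb)))
    for (j in seq_along(pct)) {
      ok <- d <= model$ad_grid$thresholds[j]
      col <- preds[!tr, j]
      col[ok] <- knn_pred[ok]
      preds[!tr, j] <- col
    }
  }

  q2 <- coverage <- numeric(length(pct))
  for (j in seq_along(pct)) {
    inn <- !is.na(preds[, j])
    coverage[j] <- mean(inn)
    q2[j] <- if (sum(inn) >= 2 && stats::var(pki[inn]) > 0)
      q_squared(pki[inn], preds[inn, j]) else NA_real_
  }

  structure(list(
    predictions = preds, max_dist = maxd, fold = fold, pki = pki,
    fold_thresholds = thr_used,
    summary = tibble::tibble(percentile = pct,
                             threshold = colMeans(thr_used),
                             coverage = coverage, q2 = q2),
    seed = seed),
    class = "cv_result")
}

#' Subset a feature_set by row
#'
#' @param features A `feature_set`.
#' @param i Logical or integer row index.
#' @return A `feature_set` for the selected compounds.
#' @export
subset_features <- function(features, i) {
  structure(list(descriptors = features$descriptors[i, , drop = FALSE],
                 fingerprints = features$fingerprints[i, , drop = FALSE],
                 ids = features$ids[i]),
            class = "feature_set")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", length(x$pki), " compounds, ",
      max(x$fold), " folds\n", sep = "")
  print(x$summary, n = 20)
  invisible(x)
}

#' Threshold-sweep report
#'
#' Tabulates, per AD threshold level, the (across-fold mean) threshold
#' value, the in-domain coverage of out-of-sample predictions, and Q2.
#'
#' @param cv A `cv_result`.
#' @return A 20-row [tibble::tibble] with columns `percentile`, `threshold`,
#'   `coverage`, `q2`.
#' @export
threshold_sweep_report <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  cv$summary
}

#' Plot Q2 and coverage against the AD threshold level
#'
#' @param cv A `cv_result`.
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(cv) {
  tab <- threshold_sweep_report(cv)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$coverage, y = .data$q2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$threshold),
                        colour = "steelblue", alpha = 0.7) +
    ggplot2::scale_size_continuous(name = "AD threshold") +
    ggplot2::labs(x = "coverage (in-domain fraction)",
                  y = expression(Q^2),
                  title = "Predictivity vs applicability-domain threshold") +
    ggplot2::theme_minimal()
}

#' Plot observed vs out-of-sample predicted pKi
#'
#' @param cv A `cv_result`.
#' @param percentile AD threshold level to plot (default 100).
#' @return A ggplot object.
#' @export
plot_cv_scatter <- function(cv, percentile = 100) {
  j <- match(paste0("p", percentile), colnames(cv$predictions))
  if (is.na(j)) stop("percentile must be one of 5, 10, ..., 100")
  df <- tibble::tibble(observed = cv$pki, predicted = cv$predictions[, j])
  df <- df[!is.na(df$predicted), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, colour = "steelblue") +
    ggplot2::labs(x = "experimental pKi", y = "out-of-sample predicted pKi") +
    ggplot2::theme_minimal()
}
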