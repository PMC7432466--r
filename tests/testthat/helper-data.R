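# Shared fixtures, built once per test run and cached.  The "study
# conditions" dataset is the one used by the heavier model checks: 300
# grammar-generated structures, latent activities correlated at 0.7,
# measurement noise of 0.2 pKi units.

.fixture_env <- new.env(parent = emptyenv())

study_dataset <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  smi <- generate_structures(300, seed = 11)
  cfg <- synth_config(seed = 11)
  truth <- assign_true_pki(smi, cfg)
  std <- standardize_structures(smi[truth$ok])
  features <- featurize_compounds(std$mol, ids = std$inchikey)
  pki_true <- truth$pki_cb2[truth$ok]
  set.seed(99)
  pki_obs <- pki_true + rnorm(length(pki_true), 0, cfg$noise_sd)
  .fixture_env$study <- list(config = cfg, truth = truth, std = std,
                             features = features, pki_true = pki_true,
                             pki_obs = pki_obs)
  .fixture_env$study
}

# A small featurized set for fast model-level tests (60 compounds).
small_feature_set <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  smi <- generate_structures(60, seed = 5)
  std <- standardize_structures(smi)
  std <- std[std$ok, ]
  features <- featurize_compounds(std$mol, ids = std$inchikey)
  .fixture_env$small <- list(std = std, features = features)
  .fixture_env$small
}

# Brute-force k-nearest-neighbour oracle: full pairwise double loop.
brute_knn <- function(query, ref, k, exclude_self = FALSE) {
  nq <- nrow(query)
  idx <- matrix(NA_integer_, nq, k)
  dst <- matrix(NA_real_, nq, k)
  for (i in seq_len(nq)) {
    d <- apply(ref, 1, function(r) sqrt(sum((query[i, ] - r)^2)))
    if (exclude_self) d[i] <- Inf
    ord <- order(d)[seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- d[ord]
  }
  list(idx = idx, dist = dst)
}

# Brute-force AUC oracle: concordant-pair counting with half-credit ties.
brute_auc <- function(score, active, lower_is_better = TRUE) {
  g <- if (lower_is_better) -score else score
  a <- g[active]
  d <- g[!active]
  tot <- 0
  for (x in a) for (y in d) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(d))
}

# Build a clean activity tibble for hand-constructed curation cases.
activity_row <- function(smiles, pki = NULL, value = NULL, type = "Ki",
                         unit = "nM", relation = "=", doc = "DOC1",
                         conf = 9L, target = "CB2") {
  if (is.null(value)) value <- 10^(9 - pki)
  tibble::tibble(smiles = smiles, standard_type = type,
                 standard_value = value, standard_units = unit,
                 standard_relation = relation, document_id = doc,
                 confidence_score = conf, target = target)
}
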