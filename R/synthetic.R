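# Synthetic data with known ground truth: structure generation from a
# scaffold-substituent grammar, latent CB1/CB2 activity functions driven by
# computed descriptors, raw activity tables with every curation-funnel
# violation represented, and docking-score lists with a tunable
# active/decoy separation.

# Scaffold templates (two substituent slots each) and substituents.  The
# substituent strings carry their own parentheses so an empty string leaves a
# valid SMILES; substituent ring digits start at 3 to avoid clashing with
# scaffold ring closures.
.SCAFFOLDS <- c(
  benzene    = "c1cc%scc%sc1",
  pyridine   = "c1cc%scc%sn1",
  chromane   = "O1CCc2cc%scc%sc2C1",
  naphthalene = "c1ccc2cc%scc%sc2c1",
  bibenzyl   = "c1cc%sccc1CCc1cc%sccc1",
  anilide    = "c1cc%sccc1C(=O)Nc1cc%sccc1OCCCC",
  dibenzamide = "c1cc%sccc1C(=O)NCCCCNC(=O)c1cc%sccc1Oc3ccccc3"
)

.SUBSTITUENTS <- c(
  "", "(C)", "(CC)", "(CCC)", "(CCCCC)", "(CCCCCCCC)", "(CCCCCCCCCCCC)",
  "(O)", "(OC)", "(OCC)", "(N)", "(N(C)C)", "(CCN(CC)CC)",
  "(F)", "(Cl)", "(Br)", "(C(F)(F)F)",
  "(C(=O)O)", "(C(=O)OC)", "(C(=O)N)", "(C#N)", "(CC(C)C)",
  "(S(=O)(=O)N)", "(c3ccccc3)", "(Oc3ccccc3)", "(C(=O)c3ccccc3)"
)

.INVALID_SMILES <- c("C1CC", "(((", "", "Q123")

#' Synthetic-data configuration
#'
#' Bundles the knobs of the synthetic generator.  The defaults describe the
#' study conditions used throughout the package's own validation: 300
#' compounds, measurement noise of 0.2 pKi units, a CB1-CB2 activity
#' correlation of 0.7, and small fractions of every kind of dirty record the
#' curation funnel must remove.
#'
#' @param n_compounds Number of structures (default 300).
#' @param n_documents Number of source documents/assays (default 8).
#' @param duplicate_rate Per-structure probability weight of replicate
#'   measurements (default 0.2).
#' @param noise_sd Measurement noise on pKi, in pKi units (default 0.2).
#' @param confidence_score_mix Named probability vector over confidence
#'   scores.
#' @param fraction_invalid_structures Fraction of structures replaced by
#'   invalid/missing entries (default 0.05).
#' @param fraction_non_ki_types Fraction of records reported as a non-Ki
#'   standard type (default 0.05).
#' @param weights_shared,weights_cb1,weights_cb2 Named descriptor weights of
#'   the latent activity functions.
#' @param cb1_cb2_correlation Target correlation between the two latent
#'   activities (default 0.7).
#' @param pki_center,pki_amplitude Location and scale of latent pKi values
#'   (defaults 7 and 1.2; values are clamped to `[4, 10]`).
#' @param seed Mandatory integer seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 300, n_documents = 8,
                         duplicate_rate = 0.2, noise_sd = 0.2,
                         confidence_score_mix = c(`9` = 0.55, `8` = 0.3,
                                                  `7` = 0.1, `5` = 0.05),
                         fraction_invalid_structures = 0.05,
                         fraction_non_ki_types = 0.05,
                         weights_shared = c(logP = 0.5, mw_graph = 0.3,
                                            TPSA = -0.4, n_rings = 0.4,
                                            chi1 = 0.3),
                         weights_cb1 = c(HBD = 0.6, n_rot_bonds = -0.4,
                                         n_halogen = 0.4),
                         weights_cb2 = c(n_oxygen = 0.5, wiener = -0.3,
                                         n_nitrogen = 0.4),
                         cb1_cb2_correlation = 0.7,
                         pki_center = 7, pki_amplitude = 1.2,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(duplicate_rate >= 0, duplicate_rate <= 1, noise_sd >= 0,
            fraction_invalid_structures >= 0,
            fraction_invalid_structures <= 1,
            fraction_non_ki_types >= 0, fraction_non_ki_types <= 1,
            cb1_cb2_correlation >= -1, cb1_cb2_correlation <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate synthetic SMILES structures
#'
#' Draws unique scaffold-substituent combinations from a combinatorial
#' grammar of substituted aromatics and fused bicyclics spanning roughly
#' 80-550 Da.  A configurable fraction of entries is replaced by deliberately
#' invalid or missing structure strings so curation always has prey.
#'
#' @param n Number of entries.
#' @param seed Integer seed.
#' @param fraction_invalid Fraction of entries replaced by invalid/missing
#'   strings (default 0).
#' @return Character vector of length `n`.
#' @export
generate_structures <- function(n, seed, fraction_invalid = 0) {
  stopifnot(n >= 1)
  n_comb <- length(.SCAFFOLDS) * length(.SUBSTITUENTS)^2
  if (n > n_comb) stop("at most ", n_comb, " unique structures available")
  set.seed(seed)
  combo <- sample(n_comb, n)
  ns <- length(.SUBSTITUENTS)
  core <- (combo - 1) %/% (ns * ns) + 1
  s1 <- ((combo - 1) %/% ns) %% ns + 1
  s2 <- (combo - 1) %% ns + 1
  smiles <- sprintf(.SCAFFOLDS[core], .SUBSTITUENTS[s1], .SUBSTITUENTS[s2])
  n_bad <- floor(fraction_invalid * n)
  if (n_bad > 0) {
    bad_at <- sample(n, n_bad)
    smiles[bad_at] <- rep_len(.INVALID_SMILES, n_bad)
  }
  unname(smiles)
}

# Standardize a weight-driven linear score of descriptor columns to unit
# sample variance; all-zero weights (or constant scores) give a zero vector.
.latent_score <- function(z, w) {
  w_use <- w[names(w) %in% colnames(z)]
  if (!length(w_use)) return(rep(0, nrow(z)))
  s <- as.numeric(z[, names(w_use), drop = FALSE] %*% w_use)
  if (stats::sd(s) == 0) return(rep(0, length(s)))
  as.numeric(scale(s))
}

# Residualize b against the columns of A (in-sample Gram-Schmidt), then
# re-standardize; returns zeros when the residual is degenerate.
.residualize <- function(b, A) {
  if (stats::sd(b) == 0) return(b)
  r <- stats::lm.fit(cbind(1, A), b)$residuals
  if (stats::sd(r) == 0) return(rep(0, length(r)))
  as.numeric(scale(r))
}

#' Assign latent CB1/CB2 pKi values to structures
#'
#' The latent activities are deterministic functions of computed molecular
#' descriptors — a shared component plus target-specific components — mixed
#' so that the in-sample correlation between the CB1 and CB2 activities
#' equals `cb1_cb2_correlation` (before clamping to `[4, 10]`).  Because the
#' activity is driven by descriptors the model actually sees, a QSAR model
#' can genuinely learn it.
#'
#' @param smiles Character vector of structures (invalid entries yield NA).
#' @param config A [synth_config()].
#' @return Tibble with `smiles`, `ok`, `pki_cb1`, `pki_cb2` (NA for invalid
#'   structures).
#' @export
assign_true_pki <- function(smiles, config) {
  stopifnot(inherits(config, "synth_config"))
  std <- standardize_structures(smiles)
  ok <- std$ok
  out <- tibble::tibble(smiles = std$input, ok = ok,
                        pki_cb1 = NA_real_, pki_cb2 = NA_real_)
  if (!any(ok)) return(out)
  d <- descriptor_matrix(std$mol[ok])
  d[!is.finite(d)] <- 0
  sds <- apply(d, 2, stats::sd)
  z <- d
  z[, sds > 0] <- scale(d[, sds > 0, drop = FALSE])
  z[, sds == 0] <- 0

  u <- .latent_score(z, config$weights_shared)
  v1 <- .residualize(.latent_score(z, config$weights_cb1), cbind(u))
  v2 <- .residualize(.latent_score(z, config$weights_cb2), cbind(u, v1))

  rho <- config$cb1_cb2_correlation
  a <- config$pki_amplitude
  p1 <- config$pki_center + a * (sqrt(abs(rho)) * u + sqrt(1 - abs(rho)) * v1)
  p2 <- config$pki_center + a * (sign(rho) * sqrt(abs(rho)) * u +
                                   sqrt(1 - abs(rho)) * v2)
  out$pki_cb1[ok] <- pmin(10, pmax(4, p1))
  out$pki_cb2[ok] <- pmin(10, pmax(4, p2))
  out
}

#' Generate a raw activity table for one target
#'
#' Emits one record per measurement in the activity-export schema consumed
#' by [curate_activity_data()]: replicate measurements with Gaussian pKi
#' noise back-converted to Ki in nM, uneven document sizes (so some assays
#' fall below the large-assay cut), a mix of confidence scores, a fraction
#' of non-Ki standard types, and the invalid/missing structures passed in.
#'
#' @param truth Tibble from [assign_true_pki()].
#' @param config A [synth_config()].
#' @param target `"CB1"` or `"CB2"`.
#' @param seed Seed for this table (defaults to `config$seed`, offset by
#'   target).
#' @return Activity-record tibble in the internal schema of
#'   [load_activity_table()].
#' @export
generate_activity_table <- function(truth, config, target = c("CB1", "CB2"),
                                    seed = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(config, "synth_config"))
  if (is.null(seed)) seed <- config$seed + match(target, c("CB1", "CB2"))
  set.seed(seed)
  pki <- if (target == "CB1") truth$pki_cb1 else truth$pki_cb2
  n <- nrow(truth)

  n_meas <- 1L + stats::rbinom(n, 2L, config$duplicate_rate)
  idx <- rep(seq_len(n), n_meas)
  m <- length(idx)

  # uneven document sizes: weight documents by squared rank so the smallest
  # documents fall below the large-assay cut
  doc_w <- (seq_len(config$n_documents))^2
  doc <- sample(config$n_documents, m, replace = TRUE,
                prob = doc_w / sum(doc_w))

  conf_vals <- as.integer(names(config$confidence_score_mix))
  conf <- conf_vals[sample.int(length(conf_vals), m, replace = TRUE,
                               prob = config$confidence_score_mix)]

  pki_meas <- pki[idx] + stats::rnorm(m, 0, config$noise_sd)
  value_nm <- 10^(9 - pki_meas)

  std_type <- rep("Ki", m)
  n_nonki <- floor(config$fraction_non_ki_types * m)
  if (n_nonki > 0) std_type[sample(m, n_nonki)] <- "IC50"

  smi <- truth$smiles[idx]
  smi[is.na(smi) | !nzchar(smi)] <- NA_character_
  tibble::tibble(
    smiles = smi,
    standard_type = std_type,
    standard_value = round(value_nm, 4),
    standard_units = "nM",
    standard_relation = "=",
    document_id = sprintf("DOC%03d", doc),
    confidence_score = conf,
    target = target
  )
}

#' Generate a docking-score list with a target ROC AUC
#'
#' Scores are drawn from the binormal model: decoys from N(0, 1) and actives
#' from N(-sep, 1) with `sep = sqrt(2) * qnorm(target_auc)` (lower scores
#' better), so the expected AUC equals `target_auc`.
#'
#' @param ligand_id Character vector of ligand identifiers.
#' @param active Logical vector labelling actives.
#' @param target_auc Expected AUC in `[0.5, 1)` (a value of 1 is
#'   approximated by a very large separation).
#' @param seed Integer seed.
#' @return Tibble with `ligand_id`, `score`, `active`.
#' @export
generate_docking_scores <- function(ligand_id, active, target_auc, seed) {
  stopifnot(length(ligand_id) == length(active),
            target_auc >= 0.5, target_auc <= 1)
  active <- as.logical(active)
  sep <- if (target_auc >= 1) 8 else sqrt(2) * stats::qnorm(target_auc)
  set.seed(seed)
  score <- stats::rnorm(length(active), mean = ifelse(active, -sep, 0), sd = 1)
  tibble::tibble(ligand_id = ligand_id, score = score, active = active)
}
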