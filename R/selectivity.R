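# CB2-vs-CB1 selectivity screening of candidate compounds: predict pKi with
# both target models at a chosen AD threshold level, score selectivity as
# dpKi = pKi(CB2) - pKi(CB1), and score novelty as the maximum Tanimoto
# similarity to any training compound of either model.

#' Molecular-weight window filter
#'
#' Retains candidates whose standardized parent structure has a molecular
#' weight inside `[low, high]` daltons (bounds inclusive).  The default
#' 250-500 Da window targets lead-like phytochemicals.
#'
#' @param smiles Character vector of candidate SMILES.
#' @param low,high Window bounds in daltons (defaults 250 and 500).
#' @return A [tibble::tibble] of retained candidates: `input`, `smiles`
#'   (standardized), `inchikey`, `mw`, plus list-column `mol`; unparseable
#'   candidates are dropped and listed in the `rejected` attribute.
#' @export
mw_filter <- function(smiles, low = 250, high = 500) {
  std <- standardize_structures(smiles)
  mw <- rep(NA_real_, nrow(std))
  ok <- which(std$ok)
  mw[ok] <- vapply(std$mol[ok], mol_weight, numeric(1))
  keep <- !is.na(mw) & mw >= low & mw <= high
  out <- tibble::tibble(input = std$input[keep], smiles = std$smiles[keep],
                        inchikey = std$inchikey[keep], mw = mw[keep],
                        mol = std$mol[keep])
  attr(out, "rejected") <- tibble::tibble(
    input = std$input[!keep],
    reason = ifelse(std$ok[!keep], "outside_mw_window", std$reason[!keep]))
  out
}

# dpKi selectivity rule shared by the screen and the acceptance checks.
dpki_selective <- function(pki_cb1, pki_cb2, dpki_cut = 1.0) {
  (pki_cb2 - pki_cb1) >= dpki_cut
}

#' Screen candidates for CB2-selective, novel compounds
#'
#' Predicts CB1 and CB2 pKi for each candidate at the chosen AD threshold
#' level, computes the selectivity score dpKi = pKi(CB2) - pKi(CB1), and
#' finds each candidate's most Tanimoto-similar training compound across the
#' union of both models' training sets.  A candidate is flagged `selective`
#' when dpKi >= `dpki_cut` (dpKi exists only when both predictions are
#' in-domain) and `novel` when its best training-set similarity is below
#' `tc_cut`.
#'
#' @param candidates Tibble from [mw_filter()] or [standardize_structures()]
#'   (needs columns `smiles`, `inchikey` and list-column `mol`).
#' @param model_cb1,model_cb2 Trained [qsar_model][train_qsar_model] objects.
#' @param threshold_percentile AD threshold level, one of 5, 10, ..., 100
#'   (default 100).
#' @param dpki_cut Selectivity cut on dpKi (default 1.0).
#' @param tc_cut Novelty cut on the Tanimoto coefficient (default 0.5).
#' @param n_bits,radius Fingerprint parameters (must match model training).
#' @return A [tibble::tibble] of class `selectivity_results` with one row
#'   per candidate: `id`, `smiles`, `pki_cb1`, `pki_cb2`, `dpki`,
#'   `in_domain_cb1`, `in_domain_cb2`, `nearest_train_id`,
#'   `nearest_train_tc`, `selective`, `novel`.
#' @export
screen_candidates <- function(candidates, model_cb1, model_cb2,
                              threshold_percentile = 100, dpki_cut = 1.0,
                              tc_cut = 0.5, n_bits = 1024L, radius = 3L) {
  stopifnot(inherits(model_cb1, "qsar_model"),
            inherits(model_cb2, "qsar_model"), nrow(candidates) >= 1)
  feats <- featurize_compounds(candidates$mol, ids = candidates$inchikey,
                               n_bits = n_bits, radius = radius)
  p1 <- predict(model_cb1, feats, threshold_percentile = threshold_percentile)
  p2 <- predict(model_cb2, feats, threshold_percentile = threshold_percentile)

  ref_fps <- rbind(model_cb1$train_fingerprints,
                   model_cb2$train_fingerprints)
  ref_ids <- c(model_cb1$train_ids, model_cb2$train_ids)
  nt <- lapply(seq_len(nrow(feats$fingerprints)), function(i)
    nearest_tanimoto(feats$fingerprints[i, ], ref_fps))

  dpki <- p2$pki_pred - p1$pki_pred
  out <- tibble::tibble(
    id = candidates$inchikey,
    smiles = candidates$smiles,
    pki_cb1 = p1$pki_pred,
    pki_cb2 = p2$pki_pred,
    dpki = dpki,
    in_domain_cb1 = p1$in_domain,
    in_domain_cb2 = p2$in_domain,
    nearest_train_id = vapply(nt, function(x) ref_ids[x$idx], character(1)),
    nearest_train_tc = vapply(nt, `[[`, numeric(1), "tc"),
    selective = !is.na(dpki) & dpki_selective(p1$pki_pred, p2$pki_pred,
                                              dpki_cut),
    novel = vapply(nt, `[[`, numeric(1), "tc") < tc_cut
  )
  class(out) <- c("selectivity_results", class(out))
  out
}

#' Mean absolute selectivity score
#'
#' Arithmetic mean of |dpKi| over compounds with predictions at both
#' targets.
#'
#' @param results A `selectivity_results` tibble (or any tibble with a
#'   `dpki` column).
#' @return The mean absolute dpKi.
#' @examples
#' mean_abs_dpki(tibble::tibble(dpki = c(0.5, 1.5, 1.0)))  # 1
#' @export
mean_abs_dpki <- function(results) {
  d <- results$dpki[!is.na(results$dpki)]
  if (!length(d)) stop("no compounds with both predictions present")
  mean(abs(d))
}
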