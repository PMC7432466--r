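# Enrichment statistics for virtual-screening score lists: ROC AUC
# (Mann-Whitney formulation, ties counted half) and enrichment factors at
# small top fractions of the ranking.  Docking conventions apply: lower
# scores are better by default.

#' Label compounds as CB2-selective from paired pKi data
#'
#' Applies the selectivity labelling rule used to build screening-benchmark
#' actives: a compound measured against both receptors is selective iff
#' pKi(CB1) <= 5.5 and pKi(CB2) > 7 (CB2 boundary strict).
#'
#' @param cb1,cb2 Tibbles with columns `inchikey` and `pki` (curated
#'   datasets); compounds are matched by InChIKey.
#' @param cb1_max Maximum CB1 pKi (default 5.5, inclusive).
#' @param cb2_min Minimum CB2 pKi (default 7, exclusive).
#' @return A [tibble::tibble] with `inchikey`, `pki_cb1`, `pki_cb2` and
#'   logical `selective`, one row per compound present in both datasets.
#' @export
label_cb2_selective <- function(cb1, cb2, cb1_max = 5.5, cb2_min = 7) {
  common <- intersect(cb1$inchikey, cb2$inchikey)
  p1 <- cb1$pki[match(common, cb1$inchikey)]
  p2 <- cb2$pki[match(common, cb2$inchikey)]
  tibble::tibble(inchikey = common, pki_cb1 = p1, pki_cb2 = p2,
                 selective = p1 <= cb1_max & p2 > cb2_min)
}

# Goodness vector: larger = better ranked.
.goodness <- function(score, lower_is_better) {
  if (lower_is_better) -score else score
}

#' ROC AUC of a scored ligand list
#'
#' The probability that a randomly chosen active is ranked better than a
#' randomly chosen decoy, with tied scores contributing one half
#' (equivalent to the Mann-Whitney U statistic normalized by the number of
#' active-decoy pairs).
#'
#' @param score Numeric docking scores.
#' @param active Logical vector (`TRUE` = active).
#' @param lower_is_better Score polarity (default `TRUE`, the docking
#'   convention).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(-9, -8, -7, -6), c(TRUE, FALSE, TRUE, FALSE))  # 0.75
#' @export
roc_auc <- function(score, active, lower_is_better = TRUE) {
  stopifnot(length(score) == length(active), all(is.finite(score)))
  active <- as.logical(active)
  n_a <- sum(active); n_d <- sum(!active)
  if (n_a == 0 || n_d == 0)
    stop("need at least one active and one decoy")
  g <- .goodness(score, lower_is_better)
  r <- rank(g, ties.method = "average")
  (sum(r[active]) - n_a * (n_a + 1) / 2) / (n_a * n_d)
}

#' Enrichment factor at a top fraction of the ranking
#'
#' The fraction of all actives recovered in the top
#' \eqn{\lceil \text{fraction} \cdot N \rceil} ranked ligands, divided by
#' `fraction`; 1 means no enrichment over random picking.  Ties straddling
#' the cutoff contribute pro rata, rounded down: if the tied block holds a
#' fraction p of actives, the remaining slots count `floor(slots * p)`
#' actives.
#'
#' @inheritParams roc_auc
#' @param fraction Top fraction of the list, in (0, 1].
#' @return The enrichment factor (>= 0, at most `1/fraction`).
#' @examples
#' # both actives in the top 2 of 10: EF = (2/2) / 0.2 = 5
#' enrichment_factor(c(1, 2, 3:10), c(TRUE, TRUE, rep(FALSE, 8)), 0.2)
#' @export
enrichment_factor <- function(score, active, fraction,
                              lower_is_better = TRUE) {
  stopifnot(length(score) == length(active), fraction > 0, fraction <= 1)
  active <- as.logical(active)
  n <- length(score)
  n_act <- sum(active)
  if (n_act == 0) stop("need at least one active")
  top <- ceiling(fraction * n)
  g <- .goodness(score, lower_is_better)
  ord <- order(-g)
  g_sorted <- g[ord]; a_sorted <- active[ord]
  cutoff <- g_sorted[top]
  strictly_better <- g_sorted > cutoff
  n_better <- sum(strictly_better)
  hits <- sum(a_sorted[strictly_better])
  tied <- g_sorted == cutoff
  slots <- top - n_better
  block_n <- sum(tied)
  block_hits <- sum(a_sorted[tied])
  hits <- hits + floor(slots * block_hits / block_n)
  (hits / n_act) / fraction
}

#' ROC curve points for a scored ligand list
#'
#' @inheritParams roc_auc
#' @return Tibble with `fpr` and `tpr`, ordered from (0,0) to (1,1); tied
#'   scores advance as one step.
#' @export
roc_points <- function(score, active, lower_is_better = TRUE) {
  active <- as.logical(active)
  g <- .goodness(score, lower_is_better)
  ord <- order(-g)
  a <- active[ord]; gs <- g[ord]
  grp <- cumsum(!duplicated(gs))
  tp <- tapply(a, grp, sum)
  fp <- tapply(!a, grp, sum)
  tibble::tibble(
    fpr = unname(c(0, cumsum(fp) / max(sum(!active), 1))),
    tpr = unname(c(0, cumsum(tp) / max(sum(active), 1)))
  )
}

#' Enrichment report for a docking score list
#'
#' @inheritParams roc_auc
#' @param fractions Top fractions for enrichment factors (default 2%, 5%,
#'   10%).
#' @return List of class `enrichment_report`: `ef` (named vector), `auc`,
#'   `roc` (curve points), `n_actives`, `n_decoys`.
#' @export
enrichment_report <- function(score, active, fractions = c(0.02, 0.05, 0.10),
                              lower_is_better = TRUE) {
  active <- as.logical(active)
  ef <- vapply(fractions, function(f)
    enrichment_factor(score, active, f, lower_is_better), numeric(1))
  names(ef) <- paste0("EF", fractions * 100, "%")
  structure(list(
    ef = ef,
    auc = roc_auc(score, active, lower_is_better),
    roc = roc_points(score, active, lower_is_better),
    n_actives = sum(active), n_decoys = sum(!active)),
    class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("Enrichment report (", x$n_actives, " actives / ", x$n_decoys,
      " decoys)\n", sep = "")
  for (nm in names(x$ef)) cat(sprintf("  %-8s %6.3f\n", nm, x$ef[[nm]]))
  cat(sprintf("  %-8s %6.3f\n", "ROC AUC", x$auc))
  invisible(x)
}

#' Plot the ROC curve of an enrichment report
#'
#' @param x An `enrichment_report`.
#' @return A ggplot object.
#' @export
plot_roc <- function(x) {
  stopifnot(inherits(x, "enrichment_report"))
  ggplot2::ggplot(x$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", x$auc)) +
    ggplot2::theme_minimal()
}
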