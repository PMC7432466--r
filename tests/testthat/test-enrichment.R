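test_that("selectivity labelling applies both pKi boundaries", {
  cb1 <- tibble::tibble(inchikey = c("A", "B", "C", "D", "E", "F"),
                        pki = c(5.0, 5.5, 5.6, 4.0, 5.5, 9.0))
  cb2 <- tibble::tibble(inchikey = c("A", "B", "C", "D", "E", "F"),
                        pki = c(7.5, 7.0, 8.0, 7.1, 7.01, 9.5))
  lab <- label_cb2_selective(cb1, cb2)
  expect_equal(lab$selective,
               cb1$pki <= 5.5 & cb2$pki > 7)        # brute-force rule
  expect_true(lab$selective[lab$inchikey == "A"])    # both conditions hold
  expect_false(lab$selective[lab$inchikey == "B"])   # CB2 boundary strict
  expect_equal(sum(lab$selective), 3)
  # matching is by key, not row order
  lab2 <- label_cb2_selective(cb1[6:1, ], cb2)
  expect_equal(sum(lab2$selective), 3)
})

test_that("ROC AUC matches hand-counted concordant pairs", {
  expect_equal(roc_auc(c(-9, -8, -7, -6), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  # perfect ranking
  expect_equal(roc_auc(c(-9, -8, -3, -2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  # higher-is-better polarity flips the ranking
  expect_equal(roc_auc(c(-9, -8, -7, -6), c(TRUE, FALSE, TRUE, FALSE),
                       lower_is_better = FALSE), 0.25)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "decoy")
})

test_that("AUC equals the brute-force pair-counting oracle, ties included", {
  set.seed(60)
  for (rep in 1:8) {
    n <- 40
    score <- round(rnorm(n), 1)       # rounding forces ties
    active <- rbinom(n, 1, 0.3) == 1
    if (!any(active) || all(active)) next
    expect_equal(roc_auc(score, active), brute_auc(score, active),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and flips on reversal", {
  set.seed(61)
  score <- rnorm(50)
  active <- rbinom(50, 1, 0.4) == 1
  a <- roc_auc(score, active)
  expect_equal(roc_auc(exp(score), active), a)
  expect_equal(roc_auc(sign(score) * abs(score)^3, active), a)
  expect_equal(roc_auc(-score, active), 1 - a)
})

test_that("enrichment factors follow the top-fraction definition", {
  # 10 ligands, both actives in the top 2
  score <- 1:10
  active <- c(TRUE, TRUE, rep(FALSE, 8))
  expect_equal(enrichment_factor(score, active, 0.2), 5)
  expect_equal(enrichment_factor(score, active, 1.0), 1)
  # no actives in the top fraction
  expect_equal(enrichment_factor(score, rev(active), 0.2), 0)
  expect_error(enrichment_factor(score, rep(FALSE, 10), 0.2), "active")
})

test_that("EF respects its upper bound and EF(1) = 1 on random lists", {
  set.seed(62)
  for (rep in 1:10) {
    n <- 50
    score <- rnorm(n)
    active <- rbinom(n, 1, 0.2) == 1
    if (!any(active)) next
    for (f in c(0.02, 0.05, 0.1, 0.5)) {
      ef <- enrichment_factor(score, active, f)
      expect_gte(ef, 0)
      expect_lte(ef, 1 / f + 1e-9)
    }
    expect_equal(enrichment_factor(score, active, 1), 1)
  }
})

test_that("ties straddling the cutoff are included pro rata", {
  # 4 ligands tied at the best score, 2 of them active; top-2 cut takes
  # floor(2 * 2/4) = 1 active
  score <- c(1, 1, 1, 1, 5, 6, 7, 8, 9, 10)
  active <- c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 6))
  expect_equal(enrichment_factor(score, active, 0.2), (1 / 2) / 0.2)
})

test_that("ROC points run from (0,0) to (1,1) and match the AUC trapezoid", {
  set.seed(63)
  score <- rnorm(30)
  active <- rbinom(30, 1, 0.4) == 1
  pts <- roc_points(score, active)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(score, active), tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(65)
  score <- rnorm(300)
  active <- rbinom(300, 1, 0.3) == 1
  ours <- roc_auc(score, active)                  # lower score = better
  ref <- pROC::roc(response = active, predictor = score, quiet = TRUE,
                   direction = ">")               # decoys score higher
  expect_equal(ours, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("the enrichment report bundles EF, AUC and counts", {
  set.seed(64)
  dock <- generate_docking_scores(sprintf("L%03d", 1:200),
                                  rep(c(TRUE, FALSE), c(40, 160)),
                                  target_auc = 0.9, seed = 3)
  rep_ <- enrichment_report(dock$score, dock$active)
  expect_named(rep_$ef, c("EF2%", "EF5%", "EF10%"))
  expect_equal(rep_$n_actives, 40)
  expect_equal(rep_$auc, roc_auc(dock$score, dock$active))
  expect_s3_class(plot_roc(rep_), "ggplot")
})
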