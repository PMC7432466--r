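# cb2screen

Ligand-based virtual screening for CB2-selective cannabinoids in R.

Selective ligands of the cannabinoid receptor 2 (CB2) are attractive
starting points for peripherally acting analgesics, because CB2 — unlike the
centrally expressed CB1 — is found mainly in immune tissue, so CB2-selective
compounds promise analgesic and anti-inflammatory action without
psychotropic effects. `cb2screen` implements the complete ligand-based
pipeline needed to hunt for such compounds from public bioactivity data:

1. **Curation** — raw activity exports (SMILES, standard type/value/relation,
   source document, assay confidence score) are funnelled through seven
   auditable steps: structure standardization (salt stripping, canonical
   InChIKey identity), a confidence-score cut (≥ 8), a large-assay rule
   (documents grouping ≥ 10 records), Ki-family selection with conversion to
   pKi = −log₁₀(Kᵢ [M]), consistency-gated replicate merging, and removal of
   compounds with indistinguishable feature vectors.
2. **Featurization** — physicochemical + topological descriptors
   (variance-filtered at 0.05, population variance) concatenated with
   1024-bit circular fingerprints of radius 3; Tanimoto similarity for
   novelty scoring.
3. **QSAR with a confidence-aware applicability domain** — a gradient-boosted
   tree ensemble is fit to pKi (hyperparameters chosen by inner 5-fold grid
   search). Each compound is then re-represented by its *leaf-value
   embedding*: the vector of per-tree leaf outputs, a latent space in pKi
   units whose row sums reproduce the ensemble prediction exactly. A kNN
   rule (k = 3) predicts the mean experimental pKi of the nearest training
   neighbours — but only when all three lie within an applicability-domain
   (AD) threshold. Thresholds are the 5th…100th percentiles (step 5) of the
   training distribution of 3rd-neighbour distances, giving 20 confidence
   levels.
4. **Validation** — 5-fold cross-validated
   Q² = 1 − Σ(yᵢ − ŷᵢ)² / Σ(yᵢ − ȳ)², swept across all 20 AD thresholds
   together with the in-domain coverage at each level.
5. **Selectivity screening** — candidates in the 250–500 Da window are
   predicted with both target models; dpKi = pKi(CB2) − pKi(CB1) ≥ 1 flags
   selectivity and a maximum training-set Tanimoto coefficient < 0.5 flags
   novelty.
6. **Enrichment statistics** — for externally produced docking-score
   rankings: enrichment factors at 2/5/10% of the list and the ROC AUC
   (Mann–Whitney formulation, ties counted half).
7. **Synthetic data** — a scaffold–substituent SMILES grammar with latent,
   descriptor-driven CB1/CB2 activities of configurable correlation, dirty
   activity tables in which every curation step has prey, and binormal
   docking-score lists with a tunable target AUC — so the whole pipeline is
   testable offline with known ground truth.

## Worked example

```r
library(cb2screen)

cfg   <- synth_config(n_compounds = 120, seed = 42)
smi   <- generate_structures(120, seed = 42, fraction_invalid = 0.05)
truth <- assign_true_pki(smi, cfg)
tab   <- generate_activity_table(truth, cfg, "CB2")

cur <- curate_activity_data(tab, target = "CB2")
cur$report
#> Curation report [CB2]
#>   1. records loaded                       155
#>   2. standardizable structure             146
#>   3. confidence score cut                 131
#>   4. large assays only                    121
#>   5. Ki-family, exact, convertible        117
#>   6. replicates merged (consistent)       100
#>   7. unique feature vectors               100
```

155 raw measurements shrink to 100 unique, internally consistent compounds:
9 records had missing or unparseable structures, 15 came from low-confidence
assays, 10 sat in documents with fewer than 10 records, 4 were not exact
Ki-family measurements, and replicate merging collapsed the rest.

```r
model <- train_qsar_model(cur$features, cur$data$pki, target = "CB2", seed = 1)
model
#> <qsar_model> CB2 | 100 training compounds | 300 trees | k = 3

cand <- standardize_structures(generate_structures(5, seed = 7))
pred <- predict(model, featurize_compounds(cand$mol, ids = cand$inchikey),
                threshold_percentile = 50)
pred[, c("id", "pki_pred", "in_domain", "max_neighbor_distance")]
#> # A tibble: 5 × 4
#>   id                          pki_pred in_domain max_neighbor_distance
#>   <chr>                          <dbl> <lgl>                     <dbl>
#> 1 UAHYUJBEIXOLBN-UHFFFAOYSA-N     6.85 TRUE                     0.0436
#> 2 PGWMCRKMZXSYGW-UHFFFAOYSA-N    NA    FALSE                    0.181
#> 3 GKJBYQWNOZLGLP-UHFFFAOYSA-N     7.01 TRUE                     0.0505
#> 4 JAKGWADXGBGJDM-UHFFFAOYSA-N     8.11 TRUE                     0.0656
#> 5 DSIJLUQSTDDPPO-UHFFFAOYSA-N    NA    FALSE                    0.102
```

At the median AD threshold, three of five query compounds fall inside the
model's applicability domain and receive a pKi estimate (the mean of their
three nearest training neighbours in leaf-value space); the others are
declared out-of-domain rather than given an unreliable number — note their
larger neighbour distances.

For model validation, `cross_validate()` + `threshold_sweep_report()`
produce the 20-row Q²/coverage table and `plot_threshold_sweep()` the
corresponding curve; `screen_candidates()` and `enrichment_report()` cover
the screening and docking-evaluation stages.

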