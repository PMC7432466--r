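---
title: "Methods: QSAR with a leaf-embedding applicability domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSAR with a leaf-embedding applicability domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `cb2screen`, and states explicitly which design questions
were genuinely open and how they were settled.

## The problem

Predicting receptor-binding affinity (pKi, the negative base-10 logarithm of
the molar inhibition constant) from molecular structure is a regression
problem with a peculiar failure mode: any model extrapolates badly for
compounds unlike its training chemistry, and for a diverse training set
drawn from thousands of assays there is no single "safe" region. The
package therefore pairs every prediction with an *applicability domain*
(AD) decision, so a downstream selectivity screen can trade coverage
against confidence explicitly, per compound.

## Curation model

Raw bioactivity exports mix assay types, units, replicate measurements,
unparseable structures and low-quality annotations. The funnel is ordered
so that each rule sees only records that survived the previous one — the
large-assay rule in particular counts document group sizes *after* the
structure and confidence removals, because a document's effective size is
what remains usable of it:

1. load (count baseline);
2. drop records whose structure is missing or fails standardization
   (unparseable SMILES, metal complexes, polymeric attachment points);
   surviving structures are salt-stripped to the largest organic fragment,
   canonicalized, and identified by InChIKey;
3. keep confidence score ≥ 8 (direct or homologous single-protein
   assignment);
4. keep records whose source document still groups ≥ 10 records;
5. keep exact Ki-family measurements (`Ki`, `pKi`, `logKi`, `log Ki`,
   case-insensitive) and convert to pKi; censored relations (`>`, `<`, …)
   are dropped because censored values bias a regression fit; unknown units
   are rejected, never guessed;
6. merge replicates per InChIKey when their *population* standard deviation
   is below 10% of the dataset's pKi range — the whole group is dropped
   otherwise, since mutually inconsistent measurements give no defensible
   single value;
7. remove *all* members of any group with bitwise-identical feature
   vectors: such compounds (e.g. stereoisomers under a 2D representation)
   are indistinguishable to the model yet may carry different activities,
   so keeping any one of them would assign it an arbitrary label.

Decisions 5–7 resolve questions on which the curation literature is silent;
each is configurable at the function interface, and the defaults above are
what `curate_activity_data()` applies.

## Feature representation

Descriptors combine OpenBabel bulk properties (MW, logP, TPSA, molar
refractivity, H-bond donor/acceptor counts) with topological descriptors of
the heavy-atom graph (atom/bond/ring counts, connectivity chi indices,
Zagreb and Wiener indices, rotatable bonds, ~31 in total). The engine is
2D-only: no installed R component provides seeded conformer embedding with
3D descriptor blocks, and an unseeded conformer generator would break the
package's determinism guarantees. The cost is that stereoisomers collapse
to identical feature vectors; the curation funnel's step 7 removes exactly
those collisions, so the model never trains on them. Descriptor counts are
engine-specific by nature; the package records its own.

Descriptor columns with population variance (dividing by *n*) below 0.05,
or containing any non-finite value, are removed. The variance mask is
learned **on the training matrix only** and frozen; screening-time
compounds are projected onto the identical feature space. Anything else
would leak held-out information into the representation. The filtered
descriptor block is concatenated with a 1024-bit circular fingerprint of
radius 3 (ECFP-style iterative neighbourhood hashing over atomic number,
degree, formal charge, implicit-H count and ring membership), which also
drives Tanimoto novelty scoring.

## The QSAR model

A gradient-boosted regression-tree ensemble (xgboost, histogram method,
single-threaded for determinism) is fit to pKi. Hyperparameters are chosen
by grid search in an inner 5-fold cross-validation over
nrounds ∈ {100, 300}, max_depth ∈ {3, 6}, eta ∈ {0.05, 0.1} (the depth grid
replaces an "unlimited depth" option that the histogram tree grower has no
clean equivalent for; on datasets of a few hundred compounds unlimited
depthwise growth is equivalent to a large fixed depth anyway).

The ensemble itself is *not* the final predictor. Each compound is
re-represented by its **leaf-value embedding**: component *t* is the output
value of the leaf the compound reaches in tree *t*. Two properties make
this space attractive for AD estimation: its coordinates are in pKi units
(so Euclidean distance is activity-scaled, and no per-dimension rescaling
is needed), and the embedding row-sum plus the base score reproduces the
ensemble prediction exactly — a verifiable invariant the test suite
asserts. An embedding of leaf *indices* (one-hot) was the main open
alternative; leaf *values* were chosen because they preserve the magnitude
information that distinguishes "different leaf, nearly identical value"
from "different leaf, opposite end of the activity scale".

Prediction is a kNN rule in the embedding, k = 3: the *mean experimental
pKi of the three nearest training compounds*, not the ensemble output — the
boosted model serves only to shape the space. The prediction is emitted
only when all three neighbour distances are within the chosen AD threshold;
otherwise the compound is reported out-of-domain with its distance
diagnostics. Whether the neighbour average should use experimental or
model-predicted values was ambiguous; experimental values were chosen so
the kNN stage adds information beyond the ensemble rather than averaging
its own outputs.

The threshold grid is built from the training set itself: for every
training compound, the distance to its 3rd-nearest neighbour (self
excluded) is recorded, and the 5th, 10th, …, 100th percentiles of that
distribution give 20 thresholds — from "queries must sit inside the densest
5% of the training cloud" to "as far as the most isolated training
compound's own neighbourhood". Distance ties at the kth neighbour are
broken by training-set insertion order (a stable, documented rule).

## Validation

Q² = 1 − SSE/SST is computed on out-of-sample predictions from 5-fold
cross-validation, with SST centred on the mean of the *evaluated* subset:
each AD threshold defines its own evaluable population (the in-domain
out-of-sample compounds), so the baseline must be that population's mean —
using the full-dataset mean would mix populations across threshold levels.
Per fold, everything is refit from scratch on the training part: variance
mask, inner grid search, embedding, AD grid. Folds are random (seeded), not
scaffold-stratified. A threshold with fewer than two in-domain test
compounds, or a constant observed subvector, yields Q² = NA rather than an
error, since sparse coverage at tight thresholds is an expected regime.

The sweep report lists, per threshold level, the across-fold mean threshold
value, coverage, and Q²; both the threshold value and the coverage are
reported because either can serve as the x-axis of the tradeoff curve.

## Selectivity screen and enrichment statistics

Candidates are restricted to 250–500 Da (bounds inclusive; daltons of the
salt-stripped parent). Selectivity is dpKi = pKi(CB2) − pKi(CB1), defined
only when both models return in-domain predictions, with the cut applied as
dpKi ≥ 1 (at equality the choice between `>` and `≥` changes nothing
measurable on real-valued predictions; both appear in the screening
literature, and the inclusive reading is the default here). Novelty is a
maximum Tanimoto coefficient < 0.5 against the union of both training sets;
0.3 is a common stricter alternative and both cuts are plain arguments.

For docking-score rankings (lower score = better, configurable), the ROC
AUC uses the Mann–Whitney formulation — the probability that a random
active outranks a random decoy, ties counting one half. The enrichment
factor at fraction *f* is (actives in top ⌈fN⌉ / all actives) / f; tied
scores straddling the cutoff contribute pro rata, rounded down, which keeps
the statistic deterministic without favouring any tie order. EF(1) = 1 by
construction.

## Synthetic data: what it emulates, and what it does not

The generator builds structures from a scaffold–substituent grammar (7
scaffolds × 26² substituent pairs, all 4732 combinations verified
parseable), spanning roughly 95–615 Da so the 250–500 Da screening window
has mass on both sides. Latent CB1/CB2 activities are deterministic
functions of *computed descriptors* — a shared component plus
target-specific components, Gram–Schmidt-orthogonalized in-sample so the
configured CB1–CB2 correlation (default 0.7) is achieved exactly before
clamping to pKi ∈ [4, 10] — which means a QSAR model can genuinely learn
them, and a permutation of the labels genuinely destroys them. Activity
tables then add: replicate measurements with Gaussian pKi noise (default
SD 0.2) back-converted to Ki in nM, uneven document sizes, a mix of
confidence scores, non-Ki standard types, and invalid/missing structures.

The default study conditions used in the package's own validation are 300
compounds, noise 0.2, correlation 0.7, 5% invalid structures and 5% non-Ki
records; cross-validation on these conditions is the heaviest routine
check and completes in well under ten minutes on one CPU.

What passing these checks shows: the pipeline removes exactly what it
claims to remove, the model recovers a learnable descriptor-driven signal
(5-fold Q² > 0.6 at the loosest threshold), and tightening the AD raises
predictivity while lowering coverage. What it does **not** show: that real
bioactivity data are descriptor-linear, that assay noise is Gaussian, or
that real chemical series exhibit the neighbourhood structure of a
combinatorial grammar — activity cliffs, scaffold bias and inter-lab
systematic error have no synthetic counterpart here. Q² values on real
exports should be expected to be lower.

## Numerical conventions and degenerate inputs

- Population variance (÷ *n*) for both the descriptor filter and the
  replicate-consistency rule; the SD-vs-range merge rule uses the same
  convention.
- Tanimoto of two all-zero fingerprints is defined as 1 (indistinguishable
  structures).
- `to_pki()`: 1 nM → 9.0; pKi passes through; logKi (log₁₀ of molar Ki) is
  negated; non-positive Ki values and unknown units are errors.
- A constant training target, a constant observed vector in Q², fewer than
  k + 1 training embeddings, and single-class enrichment input all raise
  immediate errors rather than returning quietly wrong numbers.
- All stochastic steps (fold assignment, grammar sampling, noise, score
  simulation) consume explicit integer seeds; xgboost runs single-threaded
  so refits are bit-reproducible.

## Known limitations

- 2D features only; enantiomers are invisible (removed at curation, not
  modelled). Diastereomer-sensitive 3D descriptors would require a seeded
  conformer pipeline not currently available to the package.
- OpenBabel's InChI treats some stereocentres written with undefined or
  partial stereo as absent; structure identity is therefore slightly
  coarser than a full stereo-aware key for those inputs.
- The kNN prediction cannot extrapolate beyond the convex hull of training
  activities — by design: out-of-hull queries are the AD's job to flag.
- Charge normalization relies on canonicalization plus salt stripping;
  exotic protonation states of the same parent may map to distinct keys.
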