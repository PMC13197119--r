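---
title: "Predicting in vivo TF binding: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting in vivo TF binding: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ChIP-seq measures where a transcription factor binds, but only for the
TF-cell-type pairs someone has assayed. tfboost predicts binding
probabilities for (region, TF, cell type) triples from data that is far
cheaper to obtain — chromatin accessibility, RNA expression, binding
motifs — so that binding can be estimated for unassayed conditions. The
prediction unit is a short genomic region (at most 350 bp, the scale of a
candidate cis-regulatory element); restricting region length keeps motif
and accessibility signals local and labels unambiguous.

## Ground-truth harmonization

Reference labels arrive as overlapping short bins labeled bound (B),
ambiguous (A) or unbound (U). A bin is attributed to a region when at least
half of the bin overlaps it (`overlap_bins`, 0-based half-open
coordinates), which typically attributes 4–10 bins per region. Bin labels
are aggregated by fixed priority rules (`aggregate_labels`): ≥ 40% B → B;
≥ 20% B and ≥ 30% A → B; any B with < 20% A → A; ≥ 20% A without B → A;
otherwise U. The rules are not mutually exclusive, so the order matters; we
apply them first-match-wins in the listed order, which resolves the overlap
between the two A rules deterministically. Ambiguous regions are excluded
from both training and evaluation — they are neither trusted positives nor
trusted negatives. Regions with no attributed bins are dropped by default
(configurable to U); no external policy exists for them, and dropping is
the conservative choice.

## Motif features

Each TF has one position-probability matrix. Scores are log-odds against a
background (uniform by default, configurable to genome composition), with a
pseudocount of 0.01 added before the log so absent bases stay finite.
`scan_max_score` scans every offset on both strands and keeps the best site
among those scoring above zero — the "any positive log-odds" site
convention of standard motif scanners — returning exactly 0 when no site
qualifies, so motif-free regions are well defined.

`total_affinity` complements the max score with a Boltzmann sum
`Σ exp(score)` over all placements and strands, letting many weak sites
accumulate. This is a standard simplification of biophysical total-affinity
models: the published pipelines call an external tool whose internal energy
model we do not reproduce bit for bit; the sum-of-exponentiated-log-odds
surrogate preserves the two properties the downstream statistics rely on
(monotone growth under sequence extension, dominance of the best site).
Affinity is converted to a p-value against a control sequence set with
add-one smoothing, `p = (1 + #{controls ≥ a}) / (1 + #controls)`, and
reported as `−log(0.0001 + p)` (natural log; the floor keeps perfect
scores finite). At least ~50 controls are needed for a useful resolution;
the empirical p-value can never be exactly 0 or 1.

## Signal features

Numeric tracks (ATAC fold change, footprinting, binding priors,
conservation) are summarized per region as min / coverage-weighted mean /
max. Bases without track coverage count as 0 signal — the bedGraph gap
convention — configurable to "skip" for sparse tracks where gaps mean
missing rather than zero. ATAC means are quantile-normalized across cell
types (ties averaged) so accessibility is comparable between conditions;
we normalize per-region means rather than base-level signal, which is the
cheaper and (for 350-bp regions) nearly equivalent choice. Differential
accessibility is the target-cell mean minus the mean of the other cells'
means. Expression enters as z-scored log(1 + TPM); the z statistics are
computed once and can be frozen from a training partition and re-applied at
test time (`stats` argument) to avoid leaking test-set statistics — the
source description normalizes "across all examples" without addressing
leakage, and freezing is the defensible reading. A σ floor of 1e-8 guards
constant tables.

## TF activity

TF activity is the contribution of motif affinity to enhancer activity: we
solve `A · W = C` for `W` by least squares, where `A` (enhancers × TFs)
holds best-site scores and `C` (enhancers × tissues) holds enhancer
probabilities. Columns of `W` can be fit independently; for unregularized
least squares this equals the joint fit. A ridge penalty is available
(`lambda`), defaulting to 0 — the plain-regression reading — because the
source describes both regularized and plain variants. Rank-deficient `A`
with `lambda = 0` triggers a warning and the minimum-norm solution. `W` is
scaled by 10000 for readability and z-normalized across all entries; the
raw solution is retained as an attribute so recovery tests can compare on
the original scale.

## TF cooperation

For each cell type we split enhancers into a ubiquitous set U (the n
enhancers whose minimum accessibility across cells is highest; the realized
threshold s is whatever value makes exactly n pass, ties broken by id) and
a cell-specific set S_c (after discarding enhancers below the 25th
percentile of global mean accessibility — no published value exists, so a
quartile is used and exposed as a parameter — rank by relative deviation of
the cell mean from the enhancer's global mean and keep the top n). Bound
sets B_τ are the top k enhancers by total affinity, computed in one joint
scan over U ∪ S_c and then split — the reading consistent with scanning
"each enhancer in U ∪ S_c" — because computing top-k separately per set
would change the contingency counts. Defaults n and k scale with the
fixture (200/40 at test scale; 5000/1000 at genome scale).

Co-binding of a TF pair is tested by two-sided Fisher exact tests on the
2×2 tables over S_c and over U. The cooperation score is the log p-value
ratio `L = log(p_ubiq / p_cell)` (natural log): L is large exactly when
co-binding is significant among cell-specific enhancers but unremarkable
among ubiquitous ones. Note the orientation: a cell-type-specific
cooperative pair has a *small* p_cell, so the informative ratio puts
p_ubiq in the numerator; the package adopts this orientation so that the
stated decision rule — cooperate when `L > 2` with support `a_c ≥ 10` —
flags planted cell-specific co-binding, which we verify by simulation.
Degenerate tables (a zero margin) take p = 1 by convention. No
multiple-testing correction is applied across pairs, matching the source
procedure. Each TF's four strongest partners (highest L, deduplicated
across cells by best L, ties by name) contribute two features each —
per-enhancer binding-site count and maximum site score — zero-padded below
four partners.

## Models

All four families are gradient-boosted decision trees with a logistic
objective. The supported environment ships no gradient-boosting package,
so the booster is implemented in the package (Rcpp): second-order boosting
with exact greedy splits, L2 leaf penalty (lambda = 1), bernoulli row
subsampling, per-tree column subsampling, and min_child_weight measured in
hessian units — the same parameterization as standard XGBoost. Defaults
follow the reference configuration: 500 rounds, learning rate 0.05,
subsample 0.8, column sample 0.8, depth 6, min_child_weight 1. Training
consumes R's RNG after `set.seed(seed)`, so identical inputs and seed give
bit-identical models. Class imbalance is handled natively by the logistic
objective; no reweighting is applied. Missing feature values are imputed
as 0 before training (e.g. absent cooperation partners).

* **General**: one model over all (TF, cell) pairs; each region is
  replicated once per pair it is labeled in, so the model sees the whole
  training set and learns TF-agnostic structure.
* **TF-tuned** (two-stage transfer): the general model's predicted
  probability is appended as a feature (`general_score`) and a new model is
  trained on the TF's own rows. The score is computed in-sample by
  default, which leaks training information into the transfer feature;
  this mirrors the simplest published reading, and an out-of-fold variant
  is the obvious hardening if the leak matters at your scale.
* **TF-only / embedding-augmented**: per-TF models without transfer; the
  augmented variant joins a precomputed region × D sequence-embedding
  matrix by region id (embedding computation is out of scope; D = 16 in
  fixtures, 1024 at full scale).
* **Criss-cross ensemble**: tissues are split randomly into groups A/B and
  chromosomes into groups 1/2; four members train on the complementary
  blocks (A1/B2, A2/B1, B1/A2, B2/A1) with early stopping when validation
  AUPR fails to improve for 50 rounds, and the ensemble predicts the
  arithmetic mean of the four members. AUPR is used as the stopping metric
  because it is the evaluation metric; a validation block with a single
  class falls back to no early stopping with a warning. Chromosome-grouped
  splits keep members honest about positional generalization; by default
  the test chromosomes (chr1, chr8, chr20 on real data) never enter
  training.

## Evaluation and QC

AUPR is computed as step-wise average precision with tied scores grouped;
trapezoidal integration is avoided because it overestimates area under
heavy class imbalance. Pooled curves concatenate (score, label) pairs
across TF-cell pairs before thresholding. Baselines rank regions by the
quantile-normalized ATAC mean alone and by the motif affinity p-score
alone. `precision_threshold` returns the smallest score cutoff reaching a
target precision, with an explicit unreachable result. FRiP is the
fraction of reads whose midpoint lies in a peak (midpoints, because the
fragment-level convention is unspecified); datasets under 0.02 FRiP fail
QC and should be discarded — their labels are too noisy to train or
evaluate against. Expression entropy (bits, 0·log 0 = 0) quantifies how
tissue-specific a TF's expression is; relative performance divides a
model's AUPR by the AUPR of ranking regions by the quantitative ChIP
signal itself, an effective upper bound set by assay noise.

## The synthetic world

`generate_world` is a pure function of its config (seed mandatory). The
defaults state the testing world once: 2,000 regions of 350 bp on 3
training chromosomes plus 1 held-out, 5 TFs, 4 cell types, 2% positive
prevalence, 5% ambiguous labels assigned independently of the signal (a
simplification — real ambiguity is signal-correlated), logit noise σ = 1.
Binding follows
`w_atac·z(log ATAC) + w_motif·z(maxPWM) + w_expr·1[TPM>0] + w_coop·coop + ε`
with the intercept calibrated by root finding so the realized positive
fraction hits the target. Weights default to w_atac = 1.5, w_motif = 1.0,
w_expr = 0.5, w_coop = 0.5: accessibility first and motif second matches
the observed importance ordering of the real-data features, and
expression/cooperation act as weaker modifiers. Sequences are uniform
random DNA with TF consensus sites implanted at 15% probability, so motif
scores are computed from actual sequence rather than drawn from a
distribution; the footprint track is accessibility modulated by motif
content (`ATAC × sigmoid(motif)` + noise), reproducing its hybrid
character; a TF1–TF2 pair co-binds only in the first cell type, giving the
cooperation statistics a planted effect; and a shared-vs-TF-specific mix
(shared_frac = 0.7) gives TFs correlated effect sizes, the regime where
cross-TF transfer helps small per-TF training sets.

What the generator does not emulate: read-level noise, fragment models,
peak calling, sequence evolution, correlated ambiguity, genome-scale
region counts, and 3D genome structure. A green test therefore establishes
algorithmic correctness and the direction of the published effects
(transfer benefit, ensembling benefit, baseline ordering, footprint
hybridity) at desk scale — not real-data effect sizes.

## Numerical choices

* Empirical p-values use add-one smoothing; `−log(0.0001 + p)` uses the
  natural log (base unstated at the source; natural is assumed and tested).
* Quantile normalization averages ties.
* z-scores use a σ floor of 1e-8.
* Fisher tests are two-sided (sidedness unstated at the source);
  degenerate tables give p = 1.
* Top-k selections break ties by id, making every selection
  permutation-invariant.
* Split thresholds in trees are midpoints between adjacent distinct
  feature values; splits require positive gain and both children above
  min_child_weight.
* Average precision groups tied scores into one threshold. Note that for a
  no-skill classifier this estimator is biased above prevalence by
  Θ(1/n_pos) for continuous scores; the random-guess = prevalence identity
  is exact only as the number of positives grows (or degenerately for
  constant scores).

## Known limitations

* The in-sample transfer feature (above) can overstate the general model's
  usefulness on small TF subsets.
* The booster implements the exact-greedy subset of XGBoost; histogram
  approximation, sparsity-aware splits and monotonicity constraints are
  absent. At desk scale this is irrelevant; at 1.5M regions it would be
  slow.
* Footprinting and enhancer probabilities are consumed as precomputed
  inputs; their upstream computation is out of scope.
* Only one motif per TF is supported, and no coordinate liftover is
  performed — inputs are taken in one assembly at face value.
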