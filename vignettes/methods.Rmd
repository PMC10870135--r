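---
title: "Methods: trajectory-based prioritization of congenital disease genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-based prioritization of congenital disease genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scprio)
```

## The model

`scprio` scores every gene in a developmental single-cell atlas for its
probability of association with a congenital disease. The premise is
biological: genes whose loss causes an organ-specific malformation tend to
be needed at a particular place (cell type) and time (developmental window),
and are therefore expressed with cluster- and pseudotime-specific patterns;
LoF-tolerant housekeeping genes are expressed broadly and stably. A
supervised classifier trained to tell curated disease genes from tolerant
housekeeping genes on expression-program features generalizes to unannotated
genes, because the features require no prior functional knowledge.

The per-gene feature vector concatenates three blocks:

* **Cluster block** (4 features per cluster): mean, unbiased variance and
  fraction of expressing cells over log-normalized expression within the
  cluster, and `log2((mean_in + 1) / (mean_out + 1))` against the cluster's
  complement. The pseudocount of 1 keeps the fold change finite for silent
  genes; base 2 is the field's convention. The fraction expressing is
  computed on raw counts (`> 0`), which the normalization's zero-preservation
  makes equivalent to computing it on normalized values.
* **Trajectory block** (10 features per cluster): per cluster, cells are
  ordered on pseudotime rescaled to [0, 1], pooled into 20 equal-width bins
  (half-open intervals, last bin closed; empty bins are dropped rather than
  zero-filled so sparsely populated ends of the trajectory do not fabricate
  signal), and the binned profile is fitted with a clamped cubic B-spline
  basis of dimension 10 — "10 control points" describing the temporal shape.
  The fit is unweighted least squares with a tiny ridge (`1e-8`): bins count
  equally regardless of their cell count, and the ridge guarantees a unique
  finite solution even when fewer than 10 bins are occupied, while agreeing
  with ordinary least squares to ~1e-8 in the well-posed case. A gene absent
  from a cluster yields the all-zero coefficient vector, the exact fit of a
  zero profile.
* **Gene-intrinsic block** (up to 9 features): constraint metrics pLI, pRec,
  pNull (probabilities; where all three are present their sum is checked
  against 1 ± 0.01 and violations logged, not rejected), syn_Z, mis_Z, lof_Z
  (Z scores), GC fraction of the gene body and of the promoter window — 500
  bp upstream through 100 bp downstream of the TSS, with the TSS base
  counted as the first downstream base, mirrored on the minus strand — and
  an optional ortholog-confidence passthrough. N bases are excluded from
  the GC denominator so assembly gaps do not bias the estimate. All
  coordinates are 1-based inclusive internally; BED input is converted on
  read.

## Training classes

The positive class is a curated disease gene list passed through a
**ubiquity filter**: for each gene, its mean expression across the
sub-trajectories of a reference pseudobulk atlas is summarized by its own
mean μ and standard deviation σ, and sub-trajectories falling inside
[μ − σ, μ + σ] count as "same expression"; a gene with more than 10 such
sub-trajectories is removed as ubiquitously expressed. Note a property of
this band rule: a gene expressed in exactly one of twenty sub-trajectories
is *also* removed (its nineteen near-zero values sit inside the band) — the
rule rejects both flat profiles and single-spike profiles, keeping genes
with graded, multi-level specificity. A flat gene (σ = 0) counts every
sub-trajectory as same and is removed whenever more than 10 exist.
Candidates absent from the reference pass through with a logged warning.

The negative class is housekeeping genes that are LoF tolerant:
`pNull > pRec` and `pNull > pLI`, strict inequalities. Genes with any of the
three probabilities missing are excluded — class labels never rest on
imputed values, imputation serves prediction features only. A gene on both
lists is assigned to the positive class with a warning.

## Classification pipeline

1. **Imputation** — chained equations: missing cells start at column means;
   cycling over incomplete columns in fixed order, each column is regressed
   by ordinary least squares (with intercept) on all others using its
   observed rows, missing cells are overwritten with predictions, and the
   sweep repeats until the largest change is below `1e-3` (≤ 10 sweeps).
   Observed cells are never modified; entirely missing columns are dropped
   with a warning.
2. **Scaling** — min-max to [0, 1], fitted on the labeled genes; unlabeled
   genes are transformed with the training minima/maxima and clipped.
   Constant columns map to 0 with a warning.
3. **Balancing** — ADASYN: for each minority point, the fraction of
   majority points among its k nearest neighbors in the full data weights
   how many synthetic points it spawns (hard regions get more); each
   synthetic point is `x_i + λ (x_z − x_i)` with `x_z` drawn among the k
   nearest *minority* neighbors and `λ ~ U(0, 1)`. Because rounding the
   ratio-weighted allocation rarely hits the deficit exactly, the synthetic
   set is trimmed or topped up uniformly at random (seeded) so the classes
   end exactly equal — the balance postcondition is deterministic.
   Oversampling is always fitted inside training folds only; validation
   folds never contain synthetic points.
4. **Forest and grid search** — a random forest (bootstrap resampling,
   impurity splitting) with `num.trees`, `max.depth`, minimal node size to
   split, and terminal bucket size searched over a small grid centered on
   values that have worked for limb and heart disease models
   (`n_estimators ∈ {90, 130}`, `max_depth ∈ {15, 30}`,
   `min_samples_split ∈ {2, 5}`, `min_samples_leaf = 1`, ADASYN
   `k ∈ {5, 10}`); the criterion is mean positive-class recall over
   stratified 5-fold CV at the provisional 0.5 cut, ties resolved by grid
   order. Forests run single-threaded with fixed seeds, making the whole
   pipeline bit-reproducible.
5. **Validation** — every labeled gene receives one out-of-fold score;
   accuracy, sensitivity and precision are reported at 0.5, and the ROC
   curve/AUC come from the standard threshold sweep. Out-of-fold rather
   than training-set metrics are reported throughout: reusing the same
   genes for tuning and validation already biases metrics upward, and
   resubstitution scores would compound it.
6. **Threshold** — a Gaussian KDE (Silverman's bandwidth) of the negative
   class's out-of-fold scores is evaluated on a 0.001-step grid over [0, 1];
   the threshold is the smallest grid point at or beyond the negative mode
   where density drops below `1e-3` of its maximum. If no point qualifies
   (e.g. scores spread over the whole interval) the 99.5th percentile of
   the negative scores is used; if all scores coincide the threshold is
   that value plus one grid step. Raising `eps_frac` can only lower the
   threshold (the cut level rises, so the crossing happens earlier).
7. **Prediction** — all genes are scored; unlabeled genes above the
   threshold form the candidate list, ranked by descending score with ties
   broken lexicographically by gene id; training genes are scored but
   flagged and excluded from the list.

Feature importances (normalized mean impurity decrease) are reported per
feature and aggregated per block, both as plain sums and as the mean of
squared importances ×1000 — two defensible aggregates for "how much does a
block matter"; both are labeled in `group_importances()`.

## Input conditioning

Cell QC applies strict inequalities — a cell must have *more than* 1,000
UMIs and 500 detected genes and *less than* 10% mitochondrial content, 50%
ribosomal content and a 0.2 doublet score. Boundary cells are removed.
Criteria whose metadata column is absent are skipped with a warning, since
doublet scoring and content annotation happen upstream. Clusters holding
less than 4% of post-QC cells, or explicitly excluded ones, are dropped;
fractions are computed once, not iteratively. Normalization is library-size
scaling to 10,000 followed by `log1p` — a deliberate, configuration-visible
stand-in for variance-stabilizing transforms that must be fitted on real
data. Mitochondrial/ribosomal genes are retained as features (they are
excluded upstream only for embedding computation, and their expression
fractions are ordinary features here).

## The synthetic data generator

`simulate_dataset()` plants the exact structure the method assumes, so every
stage of the pipeline is testable without downloads. The default scenario —
3 clusters × 300 cells across 4 stages; 100 labeled disease-like genes (one
with a ubiquitous reference profile), 60 *unlabeled* disease-like genes for
recovery measurement, 300 housekeeping-like and 600 noise genes;
negative-binomial counts with dispersion 0.5; a 4-fold planted effect — is
the package's reference condition for the acceptance checks and the
problem size quoted in all end-to-end tests. At this scale the atlas-grade
QC thresholds would empty the matrix, so end-to-end runs use fixture-scale
thresholds (UMI > 100, genes > 50); QC is configuration by design.

Design choices worth knowing:

* **Disease-like genes**: 1 or 2 randomly assigned signal clusters (or, for
  ~30% of genes, a purely temporal modulation shared by all clusters — only
  the trajectory block can see those); inside a signal cluster the temporal
  shape (`bump`, `ramp` or `switch`) rises from baseline to peak, outside
  the gene sits at a flat baseline `disease_effect`-fold below the
  in-cluster mean, so `disease_effect` is the planted cluster-level fold
  change. Per-cell means are normalized so each gene's *overall* abundance
  is drawn from the same distribution as the housekeeping genes' — the
  pseudo-bulk mean carries no class signal by construction.
* **Housekeeping-like genes**: flat in expectation across clusters and
  time, but with a gene-specific inflated negative-binomial dispersion
  absorbing half the cell-level variance excess a structured gene of equal
  abundance would show. This "bursty but stable" profile blurs the
  remaining pseudo-bulk contrasts (variance, fraction expressing) without
  making their temporal profiles noisy. Their constraints are LoF-tolerant
  by construction (`pNull` strictly maximal); disease genes draw intolerant
  constraints (`pLI ~ Beta(5, 1)`, `pNull ~ Beta(1, 5)`).
* **Reference pseudobulk**: housekeeping (and designated ubiquitous
  disease) genes are flat across the 20 sub-trajectories, hence removed by
  the band rule; other disease genes get a three-tiered profile (≈7
  sub-trajectories near zero, 6 at a mid level, 7 at twice that), which
  leaves only the mid tier inside the one-σ band — a tiered profile is the
  kind of pattern the band rule *keeps*, single spikes being rejected (see
  above).
* **Genome**: two synthetic contigs with 200-bp gene bodies of per-gene GC
  bias on alternating strands, spaced so promoter windows never collide.
  GC is intentionally uninformative about class.
* A tenth of the noise genes lack all constraint values, exercising
  imputation; 2% of noise genes are entirely silent, exercising the
  retention filter.

What the generator does **not** emulate: batch effects, ambient RNA,
doublets, realistic pathway covariance between genes, cell-type
proportions changing over development, or any correlation between GC
content and disease status. Passing tests therefore demonstrate that the
pipeline recovers the planted statistical structure under idealized noise —
not that the classifier's headline numbers transfer to real atlases, where
normalization, clustering quality and trajectory inference dominate.

## Numerical choices and degenerate inputs

* Pseudotime: precomputed values are min-max rescaled per cluster (a
  cluster with a constant pseudotime maps to 0.5); the stage-rank fallback
  assigns `(stage_index + u) / n_stages` with `u` a seeded within-stage
  offset, guaranteeing the earliest stage is the root and values are
  unique. Stage labels are ordered by their first numeric component
  ("E9.5" before "E10.5").
* A pseudotime of exactly 1 falls in the last bin (closure rule).
* Singleton clusters get variance 0; single-cluster matrices are rejected
  (fold change needs a complement).
* Ties in ranked output always break lexicographically by gene id, making
  output files byte-reproducible.
* ADASYN with a minority class smaller than k + 1 reduces k with a warning;
  a fully balanced input passes through untouched.
* The model file stores a schema fingerprint; prediction refuses feature
  matrices whose column set differs from training, naming the offenders.

## Problem sizes and runtime

All shipped tests and the acceptance script run on the default synthetic
scenario (1,060 genes × 900 cells) or smaller; the full pipeline (grid
search over 16 settings × 5 folds, final fit, threshold, genome-wide
scoring) takes a few seconds on one core, and the complete test suite under
a minute. These sizes were chosen so a desk-scale run exercises every code
path, including imputation, clipping and the ablations.

## Limitations

Trajectory inference, clustering, integration and doublet detection are
upstream concerns; this package consumes their outputs. The density-zero
threshold depends on the KDE bandwidth — Silverman's rule is a convention,
and both the bandwidth's grid step and the `eps_frac` cut are exposed as
parameters. The ubiquity rule's "same expression" band is one reading of a
loosely specified filter (a pairwise-similarity reading exists); the band
interpretation is implemented because it is simplest and its edge behavior
(removing both flat and single-spike profiles) is documented and tested.
Hyperparameter search is deliberately small; users with compute to spare
should widen `hyperparameter_grid()`.
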