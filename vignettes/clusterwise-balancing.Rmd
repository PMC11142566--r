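---
title: "Cluster-wise hybrid balancing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-wise hybrid balancing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmsmote)
```

## The procedure

`kmsmote` addresses binary classification on heavily imbalanced clinical
tables (the reference setting is a thyroid screening panel with a ≈27:1
class ratio). Its core is `cluster_balance()`, a hybrid resampler that
exploits multi-modal feature structure instead of treating the minority
class as one homogeneous cloud:

1. **Standardization.** Continuous features are z-scored with the training
   mean and population standard deviation (denominator `n`); binary
   indicators pass through. All neighbour and centroid geometry downstream
   uses this scale; labels are excluded from the geometry so the target
   cannot leak into the clustering.
2. **Elbow scan.** `elbow_k()` runs seeded k-means (k-means++
   initialisation, Lloyd iterations) for `k = 1..k_max`, keeping the best
   of `restarts` runs per `k`, and chooses the `k` with the sharpest
   decrease in the within-cluster sum of squared distances (SSD). "Sharpest
   decrease" is operationalised as the maximum discrete second difference
   `SSD(k-1) - 2·SSD(k) + SSD(k+1)` over the interior `k`; a
   distance-to-chord knee rule is available via `method = "knee"`. The
   phrase is qualitative in the literature, so the operationalisation is a
   design choice; both rules recover the generator's planted cluster count.
3. **Per-cluster SMOTE.** Within each cluster, the locally rarer class is
   interpolated up to the locally more frequent count: synthetic rows are
   `x + λ(x' − x)` with `x'` one of the `k_neighbors1 = 5` nearest
   same-class neighbours of `x` *inside the cluster* and `λ ~ U[0,1)`.
   Targeting the cluster-local majority (not a global quota) keeps the
   synthetic mass inside each mode and makes the merged table
   approximately — not exactly — balanced, which is the behaviour the
   method is known for.
4. **Edited-nearest-neighbour cleaning.** Each row's `k_neighbors2`
   nearest neighbours are found in the table being edited (self excluded);
   rows whose label disagrees with the *strict majority* label of those
   neighbours are deleted. `editor = "enn"` uses 3 neighbours,
   `editor = "knn"` 5. Deletions are decided against the original table
   and applied simultaneously, so the result is order-independent; a tied
   vote keeps the row (deletion requires strict disagreement); both
   classes are subject to editing.
5. **Merge.** Clusters are concatenated. If the final class ratio leaves
   `[1/1.25, 1.25]` the report carries a warning flag rather than an
   error, since heavy label noise legitimately drives the editor outside
   the band.

Editing per cluster before merging is the default (`scope =
"per_cluster"`); a single editing pass on the merged table is available as
`scope = "global"`. The two orderings are both defensible readings of the
procedure's description in the literature; per-cluster is the default
because it keeps every step local to a mode, and the global variant is
retained for comparison.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `k_neighbors1` | 5 | SMOTE interpolation neighbours (reduced to `minority − 1` in tiny clusters) |
| `k_neighbors2` | 3 (ENN) / 5 (KNN) | editing neighbourhood size |
| `k_max` | 10 | elbow-scan upper bound; must exceed the expected mode count |
| `restarts` | 5 | k-means restarts per `k` (best SSD kept) |
| `tol`, `max_iter` | 1e-4, 300 | Lloyd convergence: stop when the largest centroid shift drops below `tol` |
| `strategy` | `"equalize"` | post-SMOTE minority target (a fixed count may be given instead) |
| `seed` | — | every random draw (k-means++ picks, SMOTE pair/λ draws, splits, shuffles) flows from it |

Clusters with fewer than two minority rows, or with no majority rows, are
passed through unmodified: interpolation needs two endpoints, and a
single-class cluster carries no imbalance to correct. Editing is skipped
for clusters with at most `k_neighbors2` rows. An emptied cluster during
Lloyd iteration is reseeded to the point farthest from its assigned
centroid. Neighbour ties are broken by ascending row index, making every
neighbour-based operation exactly reproducible; the test suite checks each
one against an exhaustive brute-force oracle.

## Surrounding protocol

`split_table()` uses `floor(ratio·n)` training rows (6916 rows at 0.8 give
the reference 5532/1384 partition) and is unstratified by default — the
reference experiment's training counts are consistent with an unstratified
split. `clean()` drops all-missing columns (the reference layout carries an
always-empty placeholder column) and rows with missing targets, then
imputes remaining cells by column median (continuous) or mode (binary);
the imputation rule is the package's own deterministic choice, since
"cleaning" is rarely specified precisely in the literature.

`run_experiment()` enforces the leakage discipline end-to-end: split,
standardize on the training side, balance the training side, then
cross-validate on the balanced training data (stability only) and report
headline metrics from the untouched test split. Reported
precision/recall/F1 are support-weighted per-class averages by default
(hence precision above accuracy on imbalanced test sets is expected;
weighted recall is algebraically equal to accuracy, which the tests assert
numerically); `average = "binary"` gives plain class-1 scores. The nine
classifier specifications ship the frozen hyperparameter defaults of the
reference protocol and bind to the standard R modelling stack through a
small adapter layer; AdaBoost is provided natively (SAMME over depth-1
stumps with learning-rate shrinkage) because no installed package exposes
it. NearMiss is fixed to version 1 (mean distance to the 3 nearest
minority rows) since the baseline's version is conventionally left
unstated.

`roc_and_auc()` sweeps thresholds over distinct score values (ties grouped
into one step) and integrates by trapezoid, which is numerically identical
to the normalised rank-sum statistic — asserted on random instances in the
tests.

## Expert concordance

`interview_rank()` tabulates a features × doctors selection matrix:
frequency is the row sum; rank 1 requires unanimity, rank 2 at least half
the panel, rank 3 otherwise. These thresholds were inferred from the
published five-doctor panel, which they fit on all twenty features, and
are documented as inferred rather than prescribed. `survey_score()`
applies 3/2/1 weights to High/Medium/Low survey counts.
`assign_levels()` cuts a score ranking into High/Medium/Low either by
fixed counts (default 2/7/11, the published partition for twenty features)
or at the two largest score gaps (`method = "gaps"`), since the cutting
rule for model-side levels is not standardised. `alignment_report()`
reports per-feature level matches, the (symmetric) match fraction, and the
Spearman correlation of the serial orders. The interview and survey are
two different instruments; the package reports both orders and does not
guess a fusion rule.

Model-side scores come from `permutation_importance()` — mean metric drop
over seeded column shuffles — so the module is fully testable without any
Shapley-value dependency; any external per-feature attribution vector can
be supplied through `importance_ranking()` instead.

## What the generator emulates — and what it does not

`generate_table()` produces tables with the reference shape: 6666/250
class counts, 21 features (15 binary indicators including the empty
placeholder, `Age`, five hormone-panel columns). The hormone columns
follow a five-component spherical Gaussian mixture with unit
within-cluster noise and centres 6 noise-units apart along distinct
hormone axes — separated enough that elbow selection is meaningful, which
is the structural premise of the method. Minority rows get additive
hormone shifts (TSH 2.0, then 1.2, 1.0, 0.8, 0.6) so the most important
feature is known by construction and moderate enough that the classes are
not trivially separable; binary indicators are Bernoulli (0.15 majority
vs 0.25 minority; `Sex` 0.5/0.6); `Age` is uninformative noise. Optional
uniform label flipping (`label_noise_frac`) gives the editors something
real to remove. `planted_truth()` exposes the latent clusters, pre-noise
labels, and intended importance order for recovery tests.

The generator is a structural stand-in, not a claim about thyroid
physiology: real hormone panels are skewed and correlated, indicators are
not independent Bernoulli draws, and real label noise is not uniform.
Passing tests therefore demonstrate that the algorithms do what they are
specified to do on data with the assumed structure — clusters, class
shifts, boundary noise — not that any particular accuracy will transfer
to a real screening table.

## Problem sizes and determinism

Unit tests run on tables of a few hundred rows; the end-to-end contract
checks use the full reference scale (6916 rows, 20 cleaned features),
where a complete `cluster_balance()` call takes a few seconds on one core.
All brute-force oracle comparisons use instances of at most 200 rows,
where exhaustive scanning is exact and fast. Every stochastic component
takes an explicit seed, and child seeds are derived with a fixed 32-bit
linear map, so identical inputs and seeds give bit-identical outputs
across runs.

## Known limitations

* Binary targets only; no multi-class or multi-label support.
* Euclidean geometry on z-scored features; SMOTE produces fractional
  values on binary indicators (inherent to interpolation), which
  downstream tree models tolerate but strict 0/1 consumers may not.
* Editing is single-pass; it is deliberately not iterated to a fixed
  point, and idempotence is not claimed.
* The elbow rule needs `k_max ≥ 3` and an interior elbow; a flat or
  non-decreasing SSD curve is flagged rather than resolved.
* With heavy label noise the edited output can leave the 1.25 balance
  band (flagged in the report); this mirrors the behaviour of the
  underlying editors rather than a defect.
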