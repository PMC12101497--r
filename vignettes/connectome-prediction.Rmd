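---
title: "Predicting working-memory components from the resting connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting working-memory components from the resting connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmconn)
```

## The model

wmconn implements a connectome-based prediction pipeline for
working-memory (WM) components. The scientific claim it operationalizes
is that stable individual differences in a behavioral component — an
event cache, an object cache, or central executive function — are
encoded in the pattern of resting-state functional connectivity, and
that the encoding is sparse enough to be localized to particular brain
networks and nodes.

The pipeline has five stages.

**Behavioral scoring.** Change-detection capacity uses Cowan's
formula $K = S(H - F)$ with set size $S$, hit rate $H$ and false-alarm
rate $F$; per subject the maximum $K$ across load conditions is taken
as capacity. Multiple-object tracking uses $K = S(2P - 1)$ with
tracking accuracy $P$. Univariate outliers beyond three standard
deviations of the grand mean are replaced by the cutoff value.
Component scores are built hierarchically from z-scored task scores:
each first-order factor is the unweighted mean of its member tasks'
z-scores (e.g. $\mathrm{BM} = \tfrac12(z_{\mathrm{PLD}} +
z_{\mathrm{Solid}})$) and each second-order factor the mean of its
first-order factors (e.g. $\mathrm{EVENT} = \tfrac12(\mathrm{BM} +
\mathrm{NBM})$).

**Connectome assembly.** Node time courses are correlated pairwise
(Pearson), Fisher-z transformed ($z = \operatorname{arctanh} r$) for
normality, and the strict upper triangle is flattened into the feature
vector: $n(n-1)/2$ edges, 35,778 for a 268-node atlas. The enumeration
is row-major over pairs $(i, j)$, $i < j$, fixed once in
`edge_index_map()` and used identically by prediction, consensus
aggregation, lesioning and endpoint lookup.

**Prediction.** A linear epsilon-SVR is trained under leave-one-out
cross-validation (LOOCV). Within each training fold — never touching
the held-out subject — all edges are ranked by the absolute weight of
an SVR fit on the full feature set, the top $q$ per mille are retained
($q \in \{1, 3, 5, 7, 9\}$; `feature_count()` floors and keeps at
least one feature, matching the 35–322 span at 268 nodes), and a fresh
SVR on the selected columns predicts the held-out subject. Accuracy is
the Pearson correlation between predicted and observed scores.
Significance comes from a permutation test that reshuffles the scores
and reruns the complete LOOCV — including feature re-selection — for
each shuffle; the primary p-value is the proportion of permuted
correlations strictly exceeding the observed one. It can be exactly
zero, so the bias-corrected $(k+1)/(n+1)$ value is reported alongside.
Benjamini–Hochberg FDR is applied across whichever comparison family a
run defines (the five thresholds of one component in `cpm_predict()`;
thresholds × networks in `lesion_scan()`; families are never pooled
across scans).

**Network importance.** Only edges selected in *every* fold (the
consensus set) are aggregated; their absolute refit weights, summed
over folds, give the between-network strength
$\mathrm{Edge}_{IJ} = \sum_{i \in I, j \in J} |e_{ij}|$. The relative
degree binarizes that matrix and takes each network's share of nonzero
entries, $\mathrm{RD}_I = \sum_J b(\mathrm{Edge}_{IJ}) \big/ \sum_I
\sum_J b(\mathrm{Edge}_{IJ})$, evaluated literally as an ordered double
sum over the symmetric matrix, so $\sum_I \mathrm{RD}_I = 1$ exactly
whenever any entry is nonzero. Node degree counts consensus edges
incident to each node of a network.

**Virtual lesions.** To test a network's necessity, all its nodes are
removed from the feature space (retaining $(n-k)(n-k-1)/2$ edges after
removing $k$ of $n$ nodes), per-mille counts are recomputed on the
reduced total, and the full prediction procedure is rerun; the scan
repeats this for every network with one FDR family across the scan.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `per_mille` | 1, 3, 5, 7, 9 | feature-selection thresholds, per mille of the edge total |
| `n_permutations` | 1000 | permutation-null size |
| `cost`, `epsilon` | 1, 0.1 | epsilon-SVR hyperparameters (libsvm defaults; the linear kernel is required for interpretable weights) |
| `tol` | 1e-3 | SMO stopping tolerance (maximal KKT violation) |
| `standardize` | off | per-fold feature z-scoring, training statistics only |
| `alpha` | 0.05 | FDR level |

Fisher-z edges share a common scale, so feature standardization is off
by default; when enabled, means and SDs come from the training fold
only and the held-out row is transformed with them.

## The synthetic-data generator

No public dataset accompanies the analysis this package implements, so
the generator is a first-class module with known ground truth.

*Time series.* Each subject's node series is stationary Gaussian with a
block correlation structure: `rho_within` (default 0.5) inside a
network, `rho_between` (default 0.1) across networks. At the cohort
level each subject's within-network correlation is jittered per network
(`subject_sd = 0.05` on the correlation scale). This trait-like
variance is what makes the simulation behave like real functional
connectivity: with a purely fixed covariance, the only between-subject
edge variance would be finite-scan sampling noise
($\approx 1/\sqrt{T-3}$), edges would have essentially no reliability,
and no behavior could be predicted from them at any realistic SNR.
With the default jitter, edge reliability (trait variance over total
variance) is about 0.7 at 500 timepoints — in the range reported for
resting-state edges.

*Behavior.* A sparse set of signal edges (default 30, both endpoints
inside one designated 20-node network, mirroring a cerebellar target)
drives the score linearly, $y = \sum_e w_e x_e + \varepsilon$, with
weights drawn once from Uniform(0.5, 1.5) — positive coupling, so
stronger within-network connectivity means higher capacity — and
Gaussian noise scaled to a requested signal-to-noise ratio
(`snr = sd(signal)/sd(noise)`, default 1.5). An "either endpoint"
placement mode exists; the default keeps both endpoints inside the
target so that lesioning it removes the signal entirely — the cleanest
necessity test.

*Trials.* The change-detection generator inverts Cowan's estimator
under the standard whole-display guessing model: with
$d = \min(K_{\mathrm{true}}/S, 1)$, hits are
$\mathrm{Bin}(n_c,\, d + (1-d)g)$ and false alarms
$\mathrm{Bin}(n_n,\, (1-d)g)$, which makes $S(H-F)$ an unbiased
estimate of $\min(K_{\mathrm{true}}, S)$. The estimator-recovery checks
use $S = 4$, guess rate 0.3, and 2,000 trials of each type, where the
estimator's standard error is ≈ 0.05 items.

*What the generator does not emulate:* hemodynamics (an AR(1) temporal
option exists but is off by default, since the pipeline consumes only
static correlation matrices), head motion, physiological noise, non-Gaussian tails, negative
within-network coupling, or any spatial embedding of nodes. Passing
tests therefore show that the pipeline recovers a linear, sparse,
network-confined signal under realistic reliability — not that real
fMRI preprocessing choices are handled; preprocessing is explicitly out
of scope.

## Numerical choices

- The LOOCV × permutation sweep is computed by a compiled epsilon-SVR
  engine (`src/svr_engine.cpp`): the linear-kernel dual depends on the
  features only through the $n \times n$ Gram matrix, so one Gram is
  precomputed and every fold/permutation/threshold is solved by
  sequential minimal optimization (second-order working-set selection,
  stopping at maximal KKT violation `tol`). Ranking weights for all
  permutations of a fold come from a single matrix product. The test
  suite cross-checks weights, intercepts and predictions against
  e1071/libsvm; agreement is at the level of the shared stopping
  tolerance (~1e-4 relative).
- Tie-break in weight ranking: equal $|w|$ resolves to the lower edge
  index, making selections deterministic (duplicated columns get equal
  weights and a fixed order).
- `feature_count()` floors ($\lfloor p \cdot q / 1000 \rfloor$,
  minimum 1): flooring reproduces the 35/322 endpoints from 35,778
  edges; rounding would give 36.
- Correlations of exactly ±1 (duplicate node series — a data defect)
  are clipped to ±(1 − 1e−7) with a warning before `arctanh`, so batch
  runs do not crash; values beyond ±1 are an error.
- Winsorization cutoffs are computed once from the original vector and
  not iterated; an SD of zero returns the input unchanged. Z-scores use
  the sample SD ($n-1$).
- Permutations are drawn from the configuration seed in a fixed order
  and the identical shuffles are reused at every threshold and for
  every lesioned network, so whole runs are bit-reproducible and
  comparable across a scan.
- A constant training target yields all-zero SVR weights; the ranking
  falls back to index order and is flagged degenerate. Degenerate folds
  are recorded without aborting the run, and a permutation whose
  predictions are constant counts as "not exceeding" the observed r.
- Edge indices are 1-based in R; serialized edge files carry the
  equivalent 0-based convention string (`"upper-row-major-0based"`).
- In `segment_and_average()`, sample time is index × TR from onset
  (0-based); the delay-phase window (default 13–15 s) is inclusive at
  both ends. The percent-signal-change baseline is a designated
  baseline condition's time course, timepoint by timepoint.

## Design decisions

Several choices were genuinely open and are recorded here as the
package's own:

- *Two SVR fits per fold.* The ranking fit (all features) and the
  prediction fit (selected features) are separate models; predicting
  with re-fitted weights on the selected subset is the standard reading
  of weight-based selection followed by prediction.
- *Consensus weights* sum $|w|$ over all folds' refit weights — the
  models that actually produced predictions — using all available
  evidence deterministically.
- *Importance threshold.* Network importance in `run_pipeline()` and
  the validation suite is computed from the consensus set of the
  best-performing (highest-r) threshold.
- *Within-network edges* contribute to the diagonal
  $\mathrm{Edge}_{II}$ and are retained in the RD double sum (the
  formula is applied literally); chord-style displays may hide the
  diagonal.
- *Lesion scans recompute per-mille counts* on the reduced edge total:
  proportional selection, not fixed counts, keeps thresholds comparable
  across differently sized lesions.
- *OBJECT-style composites* are unweighted means of their member task
  z-scores; no loading-based weighting and no logit transform of
  accuracy-based tasks.
- *The guessing model* behind the trial generator was chosen because it
  makes Cowan's K unbiased — the property the scoring layer is tested
  against.

## Problem sizes used in validation

The acceptance-level checks run 20 synthetic cohorts at the emulated
study scale — 103 subjects, 268 nodes, 10 networks, 30 signal edges in
the 20-node cerebellum network, SNR 1.5 — with 200 permutations per
threshold, and a 10-network lesion scan on the first cohort; the
permutation-null calibration uses 100 independent 30-subject, 20-node
cohorts with 99 permutations each. These sizes were chosen so the whole
suite completes in tens of minutes on a single core while keeping every
procedure at full methodological fidelity (nested selection, full
permutation reruns, literal formulas).

## Known limitations

- The permutation engine assumes exchangeability of subjects; family
  structure or site effects would need restricted permutation schemes.
- The binarized relative degree is scale-free but coarse: a single
  spurious consensus edge creates as much "degree" as a heavily
  weighted bundle, so RD localization is only as clean as the consensus
  set. With weak signal the consensus can legitimately be empty.
- LOOCV is the only cross-validation scheme, by design; k-fold
  variants, alternative learners and hyperparameter search are out of
  scope.
- The compiled SMO solver targets the $n \ll p$ regime of this
  pipeline (subjects in the low hundreds); it keeps the full Gram in
  memory and is not intended for thousands of subjects.
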