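---
title: "Iterative estimated MSA for lesion inference: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative estimated MSA for lesion inference: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmsa)
```

## The inference problem

After a stroke, the mapping from damaged tissue to behavioural deficit is
many-to-one and confounded: lesions respect vascular territories, not
functional boundaries, so regions that share a blood supply are damaged
together and mass-univariate methods cannot tell which of them the function
actually needs. This package treats the question as credit assignment in a
coalitional game. The players are `N` regions of interest (ROIs) plus one
catch-all "rest of brain" (RoB) element; a coalition is the set of *intact*
players; the payoff `v(S)` is the behavioural performance of a brain with
exactly the complement of `S` damaged. The Shapley value of a region — its
average marginal contribution over all join orders — is the unique credit
allocation satisfying efficiency (values sum to
`v(all intact) − v(all lesioned)`), symmetry, and the dummy axiom, which is
what makes it defensible as a *causal contribution* rather than an
association strength.

With this orientation a positive contribution means damage lowers
performance; negative contributions (regions whose damage improves the
score) are representable and deliberately retained during elimination.

## From cohort data to a characteristic function

A clinical cohort provides graded lesion loads (percent of each ROI's
voxels inside the lesion, 0–100) and a behavioural score. For limb motor
function the score is `10 − (upper + lower NIHSS limb items)`, range 2–10;
it is binarised at the ceiling: 10 codes intact ability (1), anything lower
a deficit (0). The package resolves the binarise-then-invert bookkeeping of
clinical scores into this single documented coding (1 = intact), which is
the orientation the game needs.

Observed patients cover a vanishing fraction of the `2^N` binary lesion
configurations, so `v` is realised by a surrogate: a random-forest
classifier trained on graded loads against the binary outcome. Querying
`v(S)` embeds the binary configuration as a graded feature vector — intact
regions at 0% load, perturbed regions at 100% ("ablation" embedding). The
forest never sees binary inputs during training, only at query time; an
alternative `"mean_load"` embedding (perturbed regions presented at their
mean observed lesion size) is available for sensitivity analysis, since a
full ablation is more extreme than anything in a typical cohort. By default
`v` returns the hard predicted class; a probability mode gives a smoother
game at the cost of leaning on the forest's (uncalibrated) vote shares.

The forest itself is implemented in compiled code (no forest package is
assumed): bagged CART trees, Gini splits, per-split feature subsampling,
and six tunable dimensions — number of trees, depth, feature fraction,
bootstrap flag, minimum leaf and minimum split size. Hyperparameters are
chosen by exhaustive grid search under stratified 5-fold cross-validation,
scored by F1 on the deficit class (the rarer, clinically relevant one; the
resampling scheme and the positive class are package choices, both
configurable). The shipped default grid is deliberately small (trees 100,
depth {5, 12}, sqrt-features, bootstrap on, min leaf {1, 4}), sized for
desk-scale cohorts; users with cluster time should widen it.

Surrogate quality is reported as leave-one-out accuracy, confusion counts
and F1, against a shuffled-label chance level: the mean LOO accuracy over
20 label permutations (count configurable), which for imbalanced outcomes
concentrates near the majority-class share — the honest baseline.

## Estimation, uncertainty, iteration

*Estimation.* Exact Shapley values require `2^N` evaluations and are kept
(capped at `N ≤ 20`) as the in-package oracle. The production estimator
samples `R` uniform permutations and averages marginal contributions; it is
unbiased with error ~ `1/√R`. Permutations are drawn independently with
replacement; coalition values are memoised within a run because prefixes
recur. Reference scale is `R = 1000`.

*Uncertainty.* `B = 1000` bootstrap resamples of patients (with
replacement, original size). Each resample retrains the surrogate and
reruns the estimator — the resampling wraps the whole pipeline, not just
the Shapley step, so the reported uncertainty includes model-fitting
variability. The contribution is the mean over resamples; the SE is the
standard deviation across resamples (not the SE of their mean — the wider,
more conservative reading of an ambiguous convention); significance is a
two-sided 95% percentile interval excluding zero, with a z-score rule as an
option. No multiple-testing correction is applied across regions by
default. Single-class resamples are redrawn and counted.

*Iteration.* Each round discards the non-RoB region with the smallest
absolute contribution — absolute, so strong negative contributors survive —
plus every region below `negligible_fraction` (default 0.01) of the total
absolute contribution, and pools them into the RoB as a
voxel-count-weighted merge. The weighted pool (rather than an unweighted
mean) makes merging associative and conserves each patient's lesioned
voxel count exactly, which the tests verify across whole runs. Ties on the
smallest contribution break towards the smaller voxel count. The loop keeps
discarding while the RoB is non-significant; a discard that turns the RoB
significant is rolled back and the previous set returned, because a
significant RoB certifies that discarded tissue carried function. The RoB
is tested from iteration one (so a badly chosen initial parcellation is
flagged immediately), hyperparameters are re-optimised every iteration (the
feature space shrinks; a freeze flag trades this for speed), and the loop
also stops when only one candidate region remains or all remaining regions
are significant positive contributors.

## The synthetic world

Clinical lesion cohorts are rarely shareable, so the generator plants a
known causal architecture in data with the right pathologies: regions are
grouped into territory blocks of 5; a Gaussian copula with within-block
correlation ρ = 0.5 drives lesion *occurrence*, so same-territory regions
are hit together (the collinearity that defeats univariate mapping);
severities are independent Beta(1.2, 3) draws scaled to [0, 100] — mostly
small lesions, occasionally near-complete ablation. Deficit follows a
weighted-load threshold: performance drops to 0 when
`Σ w_r · load_r / 100 ≥ θ`, creating the many-to-one pattern where both
large and small lesions can produce a deficit. Defaults: 300 patients, 30
regions + RoB, per-region prevalence 0.35, three causal regions (weights
1.0, 0.85, 0.7) placed at the heads of *different* blocks, θ = 0.3, 2%
label noise. These values were fixed once, a priori: ~1/5 the scale of a
typical motor-deficit cohort, a ~2:1 normal:deficit split so both classes
are learnable at n = 300 (clinical motor cohorts are more imbalanced, ~4:1),
causal regions in different territories because that is the regime in which
recovery is well-posed, and label noise at the few-percent level of
clinical misclassification. The generator self-checks: with zero noise
every label is re-derived from the threshold rule.

What a green recovery test establishes: the pipeline finds a sparse causal
set among correlated nulls at realistic sparsity and noise. What it does
not: performance under causal regions sharing one territory (their credit
splits and may drop below significance), anatomically realistic 3-D lesion
geometry, graded outcomes, or cohort sizes where the surrogate is
data-starved.

## Numerical choices and degenerate inputs

- All randomness descends from one master seed through derived sub-seeds
  (grid search, folds, bootstrap, permutations, shuffles); identical seeds
  give byte-identical outputs, including across the compiled path, which
  uses its own Mersenne Twister stream independent of R's.
- F1 is defined as 0 when `tp = 0`; LOO folds with a single training class
  still train (predicting that class) and are logged, not dropped.
- Correlations of constant lesion columns are reported as missing, never
  coerced to 0; p-values come from the t distribution with n − 2 df.
- `exact_shapley` weights use `1/(n·choose(n−1,s))`, exact in double
  precision over the whole supported range, rather than factorials.
- Degenerate games (all-zero contributions) refuse normalisation; an
  all-normal cohort refuses surrogate training with a clear error; a
  pure-noise outcome terminates the loop with an explicit "no significant
  contributors" banner rather than a fabricated set.
- Voxel extraction requires identical grids (registration is upstream and
  out of scope) and assigns unclaimed non-background atlas voxels to the
  RoB, so lesioned voxels are conserved exactly.

## Known limitations

The surrogate is the load-bearing assumption: Shapley values are computed
on the model, not on nature, and configurations far from the data manifold
(full ablations of many regions) are extrapolations. Contributions of
strongly collinear regions are split by the game's symmetry, which is
honest but can render each member individually non-significant. The RoB
dilutes small critical structures pooled into it, so a non-significant RoB
is strong but not airtight evidence of completeness. Finally, hard-class
games make `v` piecewise constant; bootstrap variability then does most of
the smoothing, and very small cohorts can show discrete jumps in
contribution estimates.
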