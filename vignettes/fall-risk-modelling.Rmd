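---
title: "Modelling trip-related fall risk from gait kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trip-related fall risk from gait kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripfall)
```

## The problem

A trip during walking forces a rapid forward balance recovery. In older
adults the outcome of a standardized laboratory trip falls into three
classes: a successful recovery (`no_fall`), a fall while lowering the tripped
foot behind the obstacle (`L_fall`), and a fall while elevating it over the
obstacle (`E_fall`). The working hypothesis of this package is that the
*regular* gait pattern — measured before any perturbation — carries enough
information to predict which of these outcomes a trip would produce.

`tripfall` implements that modelling chain end to end:

1. compute 40 spatiotemporal and sagittal-plane angular gait features from
   one gait cycle of 3D marker kinematics;
2. rank them with multiclass ReliefF and keep the top half;
3. build 20 nested feature subsets by importance-based backward elimination,
   training a bagged decision-tree ensemble on each;
4. evaluate every subset with 10 repeats of stratified 5-fold
   cross-validation, per-class one-vs-rest ROC, and accuracies at the
   default (0.5) and Youden-optimal cutoffs;
5. compare the 20 models (one-way ANOVA, post-hoc paired t-tests) and pick
   the *best* (maximum mean AUC) and *optimal* (fewest features with mean
   AUC above 0.95 x the maximum) models.

Because the underlying motion-capture cohort is not public, a synthetic-data
module generates both feature-level cohorts matching published
class-conditional summaries and marker-level walking trials with known
ground truth, so every stage is testable.

## The gait cycle and its events

All features are computed over one gait cycle bounded by four events: the
unperturbed (right) foot touchdown (`pre_TD`), the perturbed (left) foot
liftoff (`LO`) and touchdown (`post_TD`), and the next right touchdown
(`next_TD`). In the laboratory these events come from force plates; here
they are detected from kinematics alone (`detect_gait_events()`): a
touchdown is the first frame of a sustained ground-contact bout of the heel
marker (height within `height_margin = 0.03` m of its record minimum, at
least `min_run = 5` frames long), refined to the contact plateau; a liftoff
is the onset of sustained toe rise at the end of the toe's contact bout.
The refinement step compares the raw trace against the in-bout *median*
level (tolerance 2.5 mm), which keeps the detected frame within about 2
frames of truth under 2 mm marker jitter. Frames are 1-based and event
intervals are closed on both ends.

## The 40 features

The feature vector (`feature_names_full()`) covers:

- **COM state.** The whole-body centre of mass comes from a 13-segment
  rigid-body model with sex-dependent segmental masses and COM locations in
  the style of the standard adjusted anthropometric tables
  (`default_body_model()`); head and arm segments, whose markers are absent
  from the reduced 12-marker set, ride as point masses at the shoulders.
  Gait speeds are anteroposterior COM velocities: the cycle average
  (displacement over duration), the cycle maximum, and instantaneous values
  at the three events (the latter named "COM velocity at ..." as in the
  field's reporting convention). COM position relative to the posterior
  base of support (the rear heel) and the margin of stability are evaluated
  at all three events.
- **Margin of stability.** The extrapolated-COM form
  `MOS = (COM - BOS_min) + vCOM / sqrt(g / l)`, with `g` gravity and `l`
  the leg length (defaulting to the mid-hip marker height of the analysed
  cycle). The pendulum scaling is `sqrt(g/l)`: dividing a velocity by a
  frequency yields a length, so the margin stays in metres and matches the
  established extrapolated-centre-of-mass formulation.
- **Timing and geometry.** Step time (`pre_TD` to `post_TD`), swing time
  (`LO` to `post_TD`), cycle duration, cadence, step length (heel-to-heel
  anteroposterior distance between the two touchdowns), stride length, step
  width, toe clearance (maximum swing toe height), minimum mid-swing toe
  clearance, maximum swing heel height, and COM vertical excursion.
- **Angles.** All angles are sagittal-plane (x-y) `atan2` angles against
  the horizontal, in degrees: trunk (bilateral mid-shoulder over mid-hip),
  hip (hip over knee), foot (toe over heel), and the knee as the shank
  angle plus `180 - hip angle`, so a straight vertical leg reads 180.
  Angles are reported for both limbs at `LO` and `post_TD`, plus swing
  extremes for the perturbed limb and the cycle extreme for the trunk.
  Flexion extremes follow the clinical convention on these
  horizontal-referenced angles: "max knee flexion" and "max trunk flexion"
  are angle *minima* (deeper flexion = smaller angle), "max hip flexion"
  and "max foot angle" are maxima. This is the only reading consistent with
  the published scale of those features (knee ~117 degrees at peak swing
  flexion vs ~178 at touchdown).

Two printed-formula ambiguities are resolved on dimensional and symmetry
grounds: the trunk angle differences like coordinates (shoulder_x - hip_x
in the second `atan2` argument), and the MOS velocity term is scaled by
`sqrt(g/l)` as above.

## Synthetic data

**Feature-level.** `class_distribution_spec()` describes per-class Gaussian
marginals; `table1_spec()` packages the published means and SDs of the 20
top-ranked features for the 298-subject cohort (192/84/22 by class), and
`default_feature_spec()` extends it to the full 40-feature pool, giving the
20 lower-ranked features identical marginals in every class — they fell
below the top-50% relevance cut, so the generator treats them as carrying
no outcome signal. Only marginal summaries are published, so the default
correlation is the identity; a user-supplied per-class correlation matrix
is accepted for sensitivity studies. Class counts are exact (no multinomial
sampling). `attach_demographics()` adds age, gender, height and weight from
the cohort's demographic summary, independently of class — mirroring the
finding that no demographic feature survives relevance ranking.

Because overlapping Gaussian marginals with independent features cannot
reproduce the real cohort's separability (the published best model reaches
AUC 0.96; the identity-correlation synthetic cohort plateaus near 0.82), the
spec carries a `separation_boost` knob that scales each class mean's offset
from the per-feature grand mean. Boosted specs create the clearly separable
regime used by the pipeline-recovery tests; they are a test harness, not a
claim about the real data.

**Marker-level.** `generate_marker_trial()` builds a planar
(sagittal-dominant) periodic walking record for 12 markers: feet alternate a
60% stance / 40% swing cycle with heel-strike dorsiflexion (+15 degrees),
push-off plantarflexion (-25 degrees) and a brisk linear heel descent into
touchdown; knees are placed by two-link inverse kinematics between hip and
ankle (thigh 0.47 and shank 0.425 of leg length, clamped to a straight leg
when out of reach); the pelvis advances at constant speed with small
zero-mean vertical, fore-aft and mediolateral oscillations; the trunk leans
forward by a constant angle. The swing heel-bump amplitude is solved
numerically (`uniroot`) so the maximum swing toe height lands exactly on the
configured value. Ground-truth event frames and feature values are attached
to the output. The template does *not* emulate between-feature covariance,
stance-phase knee micro-flexion dynamics, arm swing, soft-tissue artefact,
or any reactive recovery — passing round-trip tests shows the extractors
are correct, not that the generator is a gait simulator.

## Feature ranking: ReliefF

`relieff_rank()` implements multiclass ReliefF with `k_neighbors = 10` (the
customary default of the algorithm family; configurable): for every
instance, the k nearest hits and, per other class, the k nearest misses are
found under Manhattan distance on range-normalized features; weights
decrease with hit differences and increase with prior-weighted miss
differences, averaged over all instances (no subsampling). Range
normalization makes the ranking invariant to affine rescaling; constant
features score zero; a class smaller than k truncates its neighbour count
with a warning. Final ties break by input feature order.
`select_top_fraction(ranking, 0.5)` keeps `round(p/2)` features (round half
up), i.e. 20 of 40.

## The ensemble and its tuning

`train_bagged_ensemble()` fits bagged CART classification trees (compiled
code under `src/`): each tree sees a bootstrap resample (n draws with
replacement, realized as weights), splits by Gini impurity, and is grown
*best-first* — the candidate leaf with the largest impurity decrease is
split next — under an explicit per-tree split budget (`max_num_splits`) and
a minimum weighted leaf size (`min_leaf_size = 5`, the study setting).
Posteriors are the mean of per-tree leaf class frequencies, so rows sum to
1 exactly. `predictor_importance()` sums each feature's impurity decrease
over splits, averages over trees and normalizes to sum to 1.

Hyperparameters (`n_learning_cycles` in [10, 500], `max_num_splits` in
[1, n-1]) are tuned by seeded random search on log-uniform grids
(`tune_hyperparams()`, default budget 30), scored by stratified 3-fold
inner-CV multiclass log-loss. Random search replaces a Bayesian optimizer
deliberately: the search space is 2-dimensional and log-spaced, a fixed
budget of 30 draws covers it densely, and the procedure is exactly
reproducible from one integer seed. If no draw fits, documented defaults
(200 cycles, n-1 splits) are returned with a warning.

`build_nested_models()` starts from the 20 selected features, repeatedly
drops the lowest-importance feature (ties drop the worse-ReliefF-ranked
one) and retrains, yielding strictly nested subsets of sizes 20 ... 1 and an
elimination record.

## Evaluation

`stratified_folds()` partitions each repeat into 5 folds preserving class
proportions: per-class counts per fold differ by at most 1, and class
remainders go to the currently smallest folds, so total fold sizes differ by
at most 1 (59-60 of 298). `evaluate_model_series()` runs every subset over
the 50 train/test splits; each split contributes one macro-averaged
one-vs-rest AUC (trapezoidal rule; a class absent from a test fold is
excluded from that split's macro average) and one accuracy value per
operating point. Accuracies aggregate by per-fold averaging.

Two operating points are reported. The default cutoff applies 0.5 to each
class posterior; the optimal cutoff maximizes Youden's J = TPR - FPR per
class. The printed description of the optimal cutoff in the source
literature ("TPR + FNR at a maximum") is degenerate — that sum is
identically 1 — so the standard Youden reading is used. J-ties resolve to
the lower threshold (the more sensitive operating point). Multiclass
assignment at per-class cutoffs follows a margin rule: among classes whose
posterior meets their cutoff (or all classes, if none do), the largest
posterior-minus-cutoff margin wins, ties to the earlier class — a
deterministic rule the scalar-cutoff description leaves open.

By default, optimal cutoffs are estimated on the training split and applied
to the test split (honest mode); `cutoff_mode = "pooled"` estimates them on
the pooled test scores instead, since the original description does not say
which was done. Similarly, `tune_mode = "fast"` (default) tunes
hyperparameters once per subset and reuses them across the 50 splits;
`"per_fold"` re-tunes on every training split at ~50x the cost. Feature
ranking and selection run once on the full table, before cross-validation,
following the order of the original protocol description; this leaks
selection information into the CV estimate, which is one reason synthetic
absolute accuracies should be read comparatively, not clinically.

`anova_one_way()` and `paired_ttest()` wrap `stats::aov()` and
`stats::t.test()`, adding only the degenerate-input conventions (all-equal
constant groups give F = 0; constant non-zero paired differences give
p = 0). No multiple-testing correction is applied to the post-hoc pairwise
tests by default, matching the original analysis; `pairwise_model_tests()`
exposes a Bonferroni option.

## Reproducibility and numerical choices

Every stochastic step takes an integer seed and restores the caller's RNG
state; child seeds are derived deterministically, so
`run_pipeline(run_config(seed = s))` is bit-reproducible and stamps every
output artifact with the seed and a config hash. Tie-breaks are
deterministic throughout (feature order in rankings, first-draw in tuning,
earlier class at margin ties, lower threshold at J ties, first feature and
lowest threshold in tree splits). Degenerate inputs are contracts, not
accidents: constant marker records raise an event-detection error naming
the limb; non-PSD correlation matrices are rejected naming the class;
single-class training data are rejected.

Problem sizes in the test suite are the package's own choices: the
structural check runs the full published configuration (298 rows, 40
features, 20 models, 50 splits, budget-30 tuning; about 2 minutes on one
core), distributional checks use 10^4-10^5 rows per class, and the
power/permutation simulations use 1,500 and 50 replicates respectively.

## Known limitations

- Synthetic cohorts share only marginal moments with the real one; absolute
  accuracies on them say nothing about clinical performance. The published
  real-data numbers (overall accuracy up to 89% / 94%, best AUC 0.96) are
  not reproducible without the original recordings.
- The marker-level generator is planar; out-of-plane kinematics exist only
  as a fixed mediolateral sway, and 3D joint-coordinate-system angles are
  out of scope.
- "Maximum gait speed" uses the anteroposterior COM velocity component, and
  the trunk segment uses bilateral marker midpoints; both are documented
  conventions where the source is silent.
- Event detection assumes level-ground walking with a clear heel-contact
  plateau; steep or crouched gait would need re-tuned thresholds.
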