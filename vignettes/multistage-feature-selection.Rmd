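---
title: "Multi-stage feature selection for cognitive aging classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage feature selection for cognitive aging classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cogsel)
```

## The problem

Structural-MRI morphometry tables are wide (hundreds of regional areas,
thicknesses, volumes and intensities) and strongly collinear: measurements
from the same region or the same segmentation family move together. Fitting a
classifier directly to such a table wastes computation, destabilizes the fit,
and returns feature sets that vary wildly between selection methods. cogsel
implements a three-stage selection algorithm designed for exactly this
regime, together with the labeling pipeline that produces its target variable
— quartile classes of a PCA-based General Cognition (GC) composite — and a
benchmark harness for comparing the full chain against its single-stage
components.

## The General Cognition composite

Four touch-screen cognitive tests enter the composite at two visits (I and
III): Fluid Intelligence (FI, number of correct answers, higher is better),
Prospective Memory (PM, binary success), Pair-Matching Memory (PMM, an error
count, higher is worse) and Reaction Time (RT, milliseconds, higher is
worse). RT and PMM have long right tails and are compressed as `log(RT)` and
`log(PMM + 1)` before any modelling; FI and PM enter untransformed.

The eight transformed columns are z-scored and the first principal component
extracted. The sign of a principal component is arbitrary, so the component
is normalized to correlate non-negatively with FI at visit I; after this flip
a larger GC score always means better cognition. Participants below the first
quartile of the GC score are labeled *Cognitive Decliners*, above the third
quartile *Positive Agers*, and the middle half *Maintainers*. Maintainers are
excluded, leaving a binary classification problem over the two extreme
groups, with `PositiveAger` as the positive class throughout the package.

Two conventions are deliberately pinned down because they change individual
labels at the margins:

* quartiles use the linear-interpolation convention (`quantile` type 7), so
  the worked example `scores = 1..8` gives q1 = 2.75 and q3 = 6.25 exactly;
* scores exactly equal to a threshold remain Maintainers — the extreme
  groups are defined by strict inequalities, which is conservative and
  deterministic.

Rows with any missing test are dropped before the PCA (mean imputation is
available via `fit_gc(..., na_action = "impute")` but is not the default:
complete-case selection matches how such cohorts are usually assembled).

Trajectory slopes are per-year changes `(S3 - S1) / (t3 - t1)`, where S1 and
S3 are per-visit composites: the same PCA procedure fitted to each visit's
four tests separately, each sign-normalized against that visit's FI. The
two-visit composite is the labeling instrument; the per-visit composites are
the trajectory instrument. They are fitted separately because a single
eight-column component has no defined per-visit value.

## The three selection stages

**Stage A — relevance and redundancy filtering.** Features whose mutual
information (MI) with the class label falls below `alpha` (nats) are dropped.
The survivors are sorted by ascending MI (ties broken by feature name so the
trace is platform-independent) and scanned greedily: whenever a pair's
absolute Pearson correlation exceeds `beta`, the lower-MI member is dropped
immediately and never reconsidered. The output provably contains no pair
with |r| > `beta`; the test suite re-verifies this with an exhaustive O(p²)
check. Absolute correlation is used because anti-correlated features are
just as redundant as correlated ones.

The MI estimator is configurable. For continuous features the default is the
k-nearest-neighbor estimator for mixed continuous/discrete pairs (k = 3),
the standard choice for continuous imaging-derived features; a seeded jitter
of relative amplitude 1e-10 breaks ties and is the stage's only stochastic
element. For categorical features the plug-in estimator over the joint table
is exact. The default `alpha` is small (0.01 nats) — at cohort sizes in the
low thousands the kNN estimate of a null feature fluctuates around zero with
a spread below 0.02 nats, so 0.01 removes a sizable fraction of pure noise
while rarely touching genuinely informative features; the L1 stage is the
stronger relevance filter and picks up what the MI screen lets through.

**Stage B — the L1 path and the smallest-adequate-C rule.** L1-regularized
logistic regression is fitted along a grid of inverse regularization
strengths `C` (25 points log-spaced on [1e-4, 1e4]); features are z-scored
with training statistics because the L1 penalty is scale-sensitive. For each
`C` the stratified 5-fold cross-validated AUC is recorded, along with the
nonzero-coefficient count of a full-data refit. The selected `C*` is the
smallest grid value whose AUC is within `epsilon` of the best AUC anywhere
to its right — the sparsest model statistically indistinguishable from the
best one. "No significant improvement" is quantified as an absolute
tolerance `epsilon = 0.005` AUC by default; a one-standard-error variant
(`rule = "one_se"`) replaces `epsilon` with the cross-fold AUC spread at the
argmax. Note the largest grid value always qualifies (the interval beyond it
is empty), so a choice always exists. The Stage B subset is the set of
features with nonzero coefficients at `C*` (|w| below 1e-10 counts as zero).

**Stage C — wrapper selection under a tuned classifier.** Sequential
*forward* selection grows a subset greedily, scoring each candidate addition
by the same stratified 5-fold cross-validated AUC used in Stage B (forward
rather than backward because the pool after Stage B is still potentially
large, and forward passes are tractable from hundreds of features). The
subset size `k` is not fixed a priori: it is searched jointly with the
classifier hyperparameters by Bayesian optimization — a Gaussian-process
surrogate with a squared-exponential kernel on the unit-cube-encoded space
and expected-improvement acquisition. Finite spaces of at most 5000
configurations are enumerated and never re-proposed, so small discrete
searches are effectively exhaustive. Because the greedy path is
deterministic given the fold seed, SFS paths are cached per classifier
configuration and trials that differ only in `k` cost almost nothing beyond
the deepest path computed so far.

The stages compose by construction: the final set is a subset of the Stage B
survivors, which are a subset of the Stage A survivors. The `trace` returned
by every stage records each dropped feature exactly once with its triggering
rule (`mi_below_alpha`, `correlated_lower_mi` with the retained partner,
`l1_zero_coef`, `sfs_not_selected`).

## Evaluation protocol

`split_cohort()` holds out a stratified test fraction (20% by default)
before anything else happens; all filtering, path fitting, wrapper search
and tuning run strictly inside the training partition. The benchmark
(`run_benchmark()`) compares three selectors — the Stage B subset alone
(`L1`), Stage C run directly on the Stage A output (`SFS`), and the full
chain (`L1+SFS`) — each paired with a tuned random forest and a tuned RBF
SVM, reporting the selected-set size N_f and accuracy, precision, recall and
AUC in percent on the untouched test set. All three selectors receive the
same Stage-A-filtered training table, so differences reflect the embedded
and wrapper stages, not the filter. SVM scores for AUC are decision values,
not calibrated probabilities: AUC is rank-based and the decision function is
rank-equivalent. Random-forest importances are mean-decrease-in-impurity
values normalized to sum to one; partial dependence clamps one feature
across a grid and averages predictions, with the 0.5 probability threshold
separating the predicted classes.

## What the synthetic cohort emulates

The generator (`synth_config()`, `generate_cohort()`) produces the structure
the pipeline assumes, with planted ground truth so selections can be scored:

* **Correlated blocks.** Each block of features shares a latent factor:
  `x = sqrt(rho) * f_block + sqrt(1 - rho) * noise`, which gives pairwise
  within-block correlation exactly `rho` in expectation (0.9 by default,
  emulating measurements of the same region across segmentation outputs).
* **Planted signal.** Features in informative blocks additionally load on a
  standard-normal latent cognition trait. The `effect_size` parameter is the
  standardized mean difference of such a feature between the bottom- and
  top-quartile latent groups — the two classes the labeling pipeline will
  extract — and is mapped internally to the latent loading
  `delta = e / sqrt(dz^2 - e^2)` with `dz ≈ 2.54` the expected gap between
  extreme quartile means of a standard normal. At the defaults
  (`rho = 0.9`, `effect_size = 0.5`) this inflates informative within-block
  correlation only to about 0.904.
* **Cognitive battery.** FI, `log(RT)` and `log(PMM + 1)` are affine in the
  latent trait plus noise, with intercepts, slopes and within-group spreads
  anchored to the scale of large population touch-screen batteries (e.g. FI
  near 8.7 vs 5.0 between extreme groups, log-RT near 6.2 vs 6.4); PM is a
  latent-threshold model. RT and PMM decrease with the latent trait (higher
  raw value = worse performance), FI and PM increase. `test_noise_sd` is a
  unitless multiplier on all residual spreads: at 0 the continuous tests are
  exact affine functions of the latent trait and PM a deterministic
  indicator, which the tests exploit as a noise-free oracle.
* **Trajectories.** The visit-III latent value drifts by
  `latent_drift * z1` per year, so below-average participants decline and
  above-average participants improve — planted trajectory directions for the
  slope analysis.
* **Demographics.** Age (negatively correlated with the latent trait by
  `age_latent_cor`), sex, education, social class and smoking are generated
  as independent categoricals/uniforms and one-hot encoded into the feature
  table; apart from age they are uninformative by construction.
* **Redundancy stress.** `near_dup_fraction` converts part of the noise pool
  into near-duplicates (r = 0.97) of informative features. The default is 0:
  a duplicate is statistically almost indistinguishable from its source, so
  under the scoring convention (duplicates belong to no block) a nonzero
  default would measure tie-breaking luck rather than selector quality. The
  stress case is exercised explicitly in the Stage A tests.

What the generator does **not** emulate: the marginal distributions, units
or covariance of real morphometry tables (a single-factor block model is a
deliberate idealization), missing data, site or scanner effects, and any
association between the non-age demographics and cognition. Passing tests on
this cohort show the algorithm recovers planted, block-structured signal
under heavy collinearity and noise — not that it would reproduce any
particular real-data result.

`score_selection()` reports `block_recall` (fraction of informative blocks
with at least one selected member — one member is enough, since the block's
signal is shared) and `false_positive_count` (selected features outside all
informative blocks; note age is genuinely informative yet counts as a false
positive under this strict convention).

## Numerical choices and degenerate inputs

* AUC is computed by `pROC` with pinned direction and levels, so no
  auto-flipping can occur; the test suite cross-checks it against an
  all-pairs Mann-Whitney tally.
* In Stage B, `C = 1 / (n * lambda)` maps the inverse-regularization grid to
  the penalized-likelihood parameterization of the underlying coordinate-
  descent solver (convergence threshold 1e-9).
* Zero-variance features: Pearson correlation is undefined, treated as r = 0
  with a logged warning in Stage A; left centered-but-unscaled in
  standardization so penalized fits see an exact zero column; a
  zero-variance *test* column is an error in the GC fit (the composite would
  be ill-defined).
* Exact MI ties in the Stage A sort are broken lexicographically by feature
  name; with equal MI the scan drops the current (lexicographically earlier)
  feature.
* The permuted-label null reported by `run_study()` retrains the final tuned
  classifier on shuffled training labels with the selected feature set
  fixed and evaluates on the untouched test set. Re-running the *selection*
  under permuted labels is not well defined here, because Stage B correctly
  refuses to return an empty model when no coefficient survives — which is
  the expected outcome under the null.
* All randomness derives from one user-facing seed, fanned out to stages via
  a deterministic hash, so any result is reproducible from a single integer.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the full pipeline on the
default cohort: 2000 participants, 30 blocks of 3 features (10 informative,
effect size 0.5), 200 noise features, about 1000 participants retained after
quartile labeling. At this size the Stage C search uses a reduced budget (8
trials over k in [4, 16] with a fixed 150-tree forest), which is ample for a
one-dimensional-plus-cache search and keeps a full study under a minute;
property checks use smaller cohorts (a few hundred participants) with the
same structure. These sizes are the package's validation conditions, chosen
so the planted effects are comfortably detectable at desk scale.

## A worked run

```{r, eval = FALSE}
study <- run_study(synth_config(), pipeline_config(), seed = 1)
study$sizes      # features entering, after A, after B, final
study$metrics    # test accuracy / precision / recall / AUC (percent)
study$recovery   # block_recall and false positives vs the planted truth
```

## Known limitations

* The GP surrogate uses a single isotropic length-scale on the encoded
  space; for the small, mostly integer spaces searched here that is
  adequate, but high-dimensional mixed spaces would warrant ARD kernels.
* Forward SFS never revisits a choice; with strongly interacting features a
  floating variant could find smaller subsets. The greedy path is what makes
  caching (and hence the joint search over k) cheap.
* The kNN MI estimator assumes a continuous feature; heavily discretized
  features should use the plug-in estimator (`mi_estimator = "discrete"`).
* Correlation pruning keeps exactly one representative per correlated
  cluster; when a cluster mixes signal and noise at similar MI, the
  representative can be the noisier member (the near-duplicate stress test
  quantifies this).
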